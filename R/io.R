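## TSV dialects: UTF-8, tab-delimited, header row, "." decimal separator,
## "NA" sentinel; fixed column orders so outputs round-trip byte-identically.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write / read a probe matrix TSV
#'
#' Dialect: columns `ProbeID`, `GeneSymbol`, then `<sample_id>.FG` and
#' `<sample_id>.BG` for each sample.
#'
#' @param pm a [probe_matrix()].
#' @param path file path.
#' @return `write_probe_matrix` returns the path invisibly;
#'   `read_probe_matrix` returns a `probe_matrix`.
#' @export
write_probe_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "probe_matrix"))
  samples <- colnames(pm$foreground)
  df <- data.frame(ProbeID = pm$probes$probe_id,
                   GeneSymbol = pm$probes$gene_symbol,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) {
    df[[paste0(s, ".FG")]] <- pm$foreground[, s]
    df[[paste0(s, ".BG")]] <- pm$background[, s]
  }
  write_tsv(df, path)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(path) {
  df <- read_tsv(path)
  if (!all(c("ProbeID", "GeneSymbol") %in% names(df)))
    stop("probe matrix TSV must start with ProbeID, GeneSymbol columns",
         call. = FALSE)
  fg_cols <- grep("\\.FG$", names(df), value = TRUE)
  samples <- sub("\\.FG$", "", fg_cols)
  bg_cols <- paste0(samples, ".BG")
  if (!all(bg_cols %in% names(df)))
    stop("every sample needs paired .FG and .BG columns", call. = FALSE)
  fg <- as.matrix(df[, fg_cols, drop = FALSE])
  bg <- as.matrix(df[, bg_cols, drop = FALSE])
  colnames(fg) <- colnames(bg) <- samples
  rownames(fg) <- rownames(bg) <- df$ProbeID
  probe_matrix(data.frame(probe_id = df$ProbeID,
                          gene_symbol = df$GeneSymbol,
                          stringsAsFactors = FALSE), fg, bg)
}

#' Write / read a sample annotation TSV
#'
#' Columns: `sample_id`, `tissue`, `treatment`, `timepoint`, `slide_id`.
#'
#' @param ann annotation `data.frame`.
#' @param path file path.
#' @return the path (write) or the annotation `data.frame` (read).
#' @export
write_annotation <- function(ann, path) {
  write_tsv(ann[, c("sample_id", "tissue", "treatment", "timepoint",
                    "slide_id")], path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) read_tsv(path)

#' Write / read a gene matrix TSV
#'
#' Columns: `feature_id`, `gene_symbol`, `n_probes_used`, then one column
#' per sample.
#'
#' @param gm a [gene_matrix()].
#' @param path file path.
#' @param stage stage tag to assume when reading.
#' @return the path (write) or a `gene_matrix` (read).
#' @export
write_gene_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "gene_matrix"))
  df <- cbind(gm$features,
              as.data.frame(gm$values, check.names = FALSE,
                            row.names = NULL))
  write_tsv(df, path)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(path, stage = "normalized") {
  df <- read_tsv(path)
  meta <- c("feature_id", "gene_symbol", "n_probes_used")
  if (!all(meta %in% names(df)))
    stop("gene matrix TSV lacks feature columns", call. = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(vals) <- df$feature_id
  gene_matrix(df[, meta], vals, stage = stage)
}

#' Write / read a qPCR Ct TSV
#'
#' Columns: `sample_id`, `tissue`, `treatment`, `timepoint`, `gene_symbol`,
#' `replicate`, `ct`.
#'
#' @param ct Ct `data.frame`.
#' @param path file path.
#' @return the path (write) or the Ct `data.frame` (read).
#' @export
write_ct_table <- function(ct, path) {
  write_tsv(ct[, c("sample_id", "tissue", "treatment", "timepoint",
                   "gene_symbol", "replicate", "ct")], path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) read_tsv(path)

#' Read a GEO series-matrix file
#'
#' Parses the standard series-matrix dialect: metadata lines prefixed `!`,
#' and a tab-delimited expression table between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers.
#' Quoted fields may contain tabs. This is an optional convenience loader;
#' no other part of the pipeline requires it.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return list with `values` (numeric matrix, rows = `ID_REF`),
#'   `samples` (a `data.frame` of per-sample `!Sample_*` metadata) and
#'   `series` (named list of `!Series_*` fields).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("series-matrix table markers missing or malformed", call. = FALSE)
  tbl <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           sep = "\t", quote = "\"", check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tbl[, -1L, drop = FALSE])
  rownames(values) <- tbl[[1L]]

  meta <- lines[seq_len(begin - 1L)]
  meta <- meta[startsWith(meta, "!")]
  parse_meta <- function(line) {
    fields <- scan(text = line, what = character(), sep = "\t",
                   quote = "\"", quiet = TRUE)
    list(key = sub("^!", "", fields[1L]), values = fields[-1L])
  }
  parsed <- lapply(meta, parse_meta)
  sample_meta <- Filter(function(p) startsWith(p$key, "Sample_"), parsed)
  samples <- if (length(sample_meta)) {
    cols <- lapply(sample_meta, `[[`, "values")
    ncols <- max(vapply(cols, length, integer(1)))
    df <- as.data.frame(lapply(cols, function(v) {
      length(v) <- ncols
      v
    }), stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- make.unique(vapply(sample_meta, `[[`, "", "key"))
    df
  } else data.frame()
  series <- Filter(function(p) startsWith(p$key, "Series_"), parsed)
  series_list <- lapply(series, `[[`, "values")
  names(series_list) <- vapply(series, `[[`, "", "key")
  list(values = values, samples = samples, series = series_list)
}
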