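#' Probe-level intensity container
#'
#' Holds per-spot foreground and local-background fluorescence for every
#' sample, together with the probe-to-gene map. Probe ids must be unique;
#' several probes may share a gene symbol.
#'
#' @param probes `data.frame` with columns `probe_id`, `gene_symbol`.
#' @param foreground,background numeric matrices (probes x samples) of raw
#'   fluorescence; row order matches `probes`, columns are sample ids.
#' @param signal optional background-corrected signal matrix.
#' @param stage processing stage tag, `"raw"` or `"background_corrected"`.
#' @return an object of class `probe_matrix`.
#' @export
probe_matrix <- function(probes, foreground, background,
                         signal = NULL, stage = "raw") {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "gene_symbol") %in% names(probes)))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in probe table", call. = FALSE)
  foreground <- as.matrix(foreground)
  background <- as.matrix(background)
  if (!identical(dim(foreground), dim(background)))
    stop("foreground and background dimensions differ", call. = FALSE)
  if (nrow(foreground) != nrow(probes))
    stop("intensity rows do not match probe table", call. = FALSE)
  if (is.null(colnames(foreground)))
    stop("foreground matrix must carry sample ids as column names",
         call. = FALSE)
  if (anyNA(foreground) || anyNA(background))
    stop("missing intensity values", call. = FALSE)
  structure(list(probes = probes, foreground = foreground,
                 background = background, signal = signal, stage = stage),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples (%d genes), stage: %s\n",
              nrow(x$foreground), ncol(x$foreground),
              length(unique(x$probes$gene_symbol)), x$stage))
  invisible(x)
}

#' Collapsed gene-level expression container
#'
#' @param features `data.frame` with columns `feature_id`, `gene_symbol`,
#'   `n_probes_used`.
#' @param values numeric matrix (features x samples).
#' @param stage one of `"background_corrected"`, `"log2"`, `"normalized"`.
#' @return an object of class `gene_matrix`.
#' @export
gene_matrix <- function(features, values,
                        stage = c("background_corrected", "log2",
                                  "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(features))
  if (any(!is.finite(values)))
    stop("non-finite expression values", call. = FALSE)
  structure(list(features = features, values = values, stage = stage),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix: %d features x %d samples, stage: %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Drop probes without an official gene symbol
#'
#' Gene filtering keeps only probes annotated with a non-empty gene symbol;
#' no live symbol validation is attempted.
#'
#' @param pm a [probe_matrix()].
#' @return a filtered `probe_matrix`.
#' @export
filter_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  keep <- !is.na(pm$probes$gene_symbol) & nzchar(pm$probes$gene_symbol)
  probe_matrix(pm$probes[keep, , drop = FALSE],
               pm$foreground[keep, , drop = FALSE],
               pm$background[keep, , drop = FALSE],
               signal = if (!is.null(pm$signal))
                 pm$signal[keep, , drop = FALSE],
               stage = pm$stage)
}

#' Subtract local background from foreground intensities
#'
#' Signal is `max(foreground - background, floor)`. The floor (1 raw unit by
#' default) keeps spots whose local background exceeds the foreground at a
#' defined low value so the subsequent log2 transform is finite.
#'
#' @param pm a [probe_matrix()] at stage `"raw"`.
#' @param floor minimum background-corrected value, in raw units.
#' @return the `probe_matrix` with `signal` filled, stage
#'   `"background_corrected"`.
#' @export
subtract_background <- function(pm, floor = 1) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (any(pm$foreground < 0) || any(pm$background < 0))
    stop("negative raw intensities", call. = FALSE)
  sig <- pmax(pm$foreground - pm$background, floor)
  probe_matrix(pm$probes, pm$foreground, pm$background,
               signal = sig, stage = "background_corrected")
}

#' Collapse probes to gene-level features
#'
#' Genes measured by fewer than 4 probes keep each probe as its own feature
#' (feature id = probe id). Genes with 4 or more probes are summarized to a
#' single feature whose per-sample value is the mean after discarding, in
#' that sample, exactly one minimum and one maximum probe value (ties at an
#' extreme lose a single instance).
#'
#' @param pm a background-corrected [probe_matrix()].
#' @return a [gene_matrix()] at stage `"background_corrected"`.
#' @export
collapse_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (pm$stage != "background_corrected" || is.null(pm$signal))
    stop("collapse_probes expects background-corrected input", call. = FALSE)
  sig <- pm$signal
  gene <- pm$probes$gene_symbol
  counts <- table(gene)
  k <- as.integer(counts[match(gene, names(counts))])

  small <- k < 4L
  feats <- list()
  vals <- list()
  if (any(small)) {
    feats[[1]] <- data.frame(feature_id = pm$probes$probe_id[small],
                             gene_symbol = gene[small],
                             n_probes_used = 1L, stringsAsFactors = FALSE)
    vals[[1]] <- sig[small, , drop = FALSE]
  }
  big_genes <- names(counts)[counts >= 4L]
  if (length(big_genes)) {
    rows <- t(vapply(big_genes, function(g) {
      m <- sig[gene == g, , drop = FALSE]
      ## remove one min and one max instance per sample
      (colSums(m) - apply(m, 2, max) - apply(m, 2, min)) / (nrow(m) - 2L)
    }, numeric(ncol(sig))))
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = big_genes, gene_symbol = big_genes,
      n_probes_used = as.integer(counts[big_genes]) - 2L,
      stringsAsFactors = FALSE)
    vals[[length(vals) + 1L]] <- rows
  }
  features <- do.call(rbind, feats)
  values <- do.call(rbind, vals)
  ## stable order: by first appearance of the feature's gene in the input
  first <- match(features$gene_symbol, gene)
  o <- order(first, match(features$feature_id, pm$probes$probe_id))
  features <- features[o, , drop = FALSE]
  values <- values[o, , drop = FALSE]
  rownames(features) <- NULL
  rownames(values) <- features$feature_id
  colnames(values) <- colnames(sig)
  gene_matrix(features, values, stage = "background_corrected")
}

#' Log2-transform a background-corrected gene matrix
#'
#' @param gm a [gene_matrix()] at stage `"background_corrected"` with all
#'   values positive (guaranteed by the background floor).
#' @return the `gene_matrix` at stage `"log2"`.
#' @export
log2_transform <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$stage != "background_corrected")
    stop("log2_transform expects a background-corrected matrix",
         call. = FALSE)
  if (any(gm$values <= 0))
    stop("nonpositive values reached log2_transform; background floor violated",
         call. = FALSE)
  gene_matrix(gm$features, log2(gm$values), stage = "log2")
}

#' Quantile-normalize a log2 gene matrix
#'
#' Classic rank-mean substitution across samples (via
#' [limma::normalizeQuantiles()] with tie averaging): after normalization
#' every sample has an identical sorted value vector; ties within a sample
#' receive the mean of the tied ranks' reference values.
#'
#' @param gm a [gene_matrix()] at stage `"log2"` with at least 2 samples.
#' @return the `gene_matrix` at stage `"normalized"`. A single-sample
#'   matrix is returned unchanged (stage advanced) with a warning.
#' @export
quantile_normalize <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$stage != "log2")
    stop("quantile_normalize expects a log2 matrix", call. = FALSE)
  if (ncol(gm$values) < 2L) {
    warning("single sample: quantile normalization is a no-op")
    return(gene_matrix(gm$features, gm$values, stage = "normalized"))
  }
  nv <- limma::normalizeQuantiles(gm$values, ties = TRUE)
  dimnames(nv) <- dimnames(gm$values)
  gene_matrix(gm$features, nv, stage = "normalized")
}

#' Raw-scale group means of a normalized gene matrix
#'
#' Inverts the log2 transform per sample and averages `2^value` over the
#' selected group's samples, giving the raw-scale mean intensities used for
#' reporting, intensity filtering and fold changes.
#'
#' @param gm a [gene_matrix()] on the log2 scale (stage `"normalized"` for
#'   the standard pipeline; stage `"log2"` is also accepted, e.g. for
#'   noise-free data where normalization has nothing to remove).
#' @param ann sample annotation `data.frame` (`sample_id`, `tissue`,
#'   `treatment`, `timepoint`, ...).
#' @param group either a character vector of sample ids, or a list with any
#'   of `tissue`, `treatment`, `timepoint` to select samples by annotation.
#' @param geometric return the geometric mean `2^mean(value)` instead of
#'   the arithmetic mean of the back-transformed per-sample values. The
#'   arithmetic default follows the reporting convention of back-transform
#'   first, then average.
#' @return named numeric vector of per-feature raw-scale group means.
#' @export
back_transform_means <- function(gm, ann, group, geometric = FALSE) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (!gm$stage %in% c("log2", "normalized"))
    stop("back_transform_means expects log2-scale values", call. = FALSE)
  ids <- select_samples(ann, group)
  ids <- intersect(ids, colnames(gm$values))
  if (!length(ids))
    stop("group selects no samples present in the matrix", call. = FALSE)
  if (geometric) 2^rowMeans(gm$values[, ids, drop = FALSE])
  else rowMeans(2^gm$values[, ids, drop = FALSE])
}

select_samples <- function(ann, group) {
  if (is.character(group)) return(group)
  stopifnot(is.list(group))
  keep <- rep(TRUE, nrow(ann))
  for (fld in c("tissue", "treatment", "timepoint"))
    if (!is.null(group[[fld]])) keep <- keep & ann[[fld]] %in% group[[fld]]
  ann$sample_id[keep]
}

#' Ratio of two raw-scale group means
#'
#' Direction is preserved: values below 1 indicate a decrease in the first
#' group relative to the second.
#'
#' @param mean_a,mean_b raw-scale group means; `mean_b` must be positive.
#' @return `mean_a / mean_b`.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_b <= 0))
    stop("fold_change: denominator mean must be > 0", call. = FALSE)
  mean_a / mean_b
}

#' Run the full preprocessing chain
#'
#' Gene filtering, background correction, probe collapse, log2 transform and
#' quantile normalization, in that order.
#'
#' @param pm a raw [probe_matrix()].
#' @param floor background-correction floor (raw units).
#' @param normalize apply quantile normalization (the default). Set to
#'   `FALSE` to stop at the log2 stage, e.g. for noise-free data or when
#'   the arrays' intensity distributions genuinely differ (strong
#'   tissue-specific expression violates the equal-distribution assumption
#'   of quantile normalization and compresses extreme cross-tissue folds).
#' @return a [gene_matrix()], stage `"normalized"` (or `"log2"`).
#' @export
preprocess_probes <- function(pm, floor = 1, normalize = TRUE) {
  gm <- log2_transform(collapse_probes(
    subtract_background(filter_probes(pm), floor = floor)))
  if (normalize) quantile_normalize(gm) else gm
}
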