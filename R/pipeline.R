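#' Assemble a pipeline configuration
#'
#' Orchestration settings for [run_pipeline()]. Inputs may be files (TSV
#' dialects written by this package) or a simulation request.
#'
#' @param output_dir directory for all stage outputs.
#' @param probe_matrix,annotation,ct_table input TSV paths, or `NULL` when
#'   `simulate` is given.
#' @param simulate a [sim_config()] to generate inputs in-run, or `NULL`.
#' @param floor background-correction floor (raw units).
#' @param sam a [sam_config()].
#' @param contrasts list of contrasts, each a list with `tissue`,
#'   `timepoint`, `treatment_a` (comparator) and `treatment_b`; `NULL`
#'   derives all treatment-versus-control (and AMPH-versus-EIH) pairs
#'   present per tissue and timepoint.
#' @param enrichment an [enrichment_config()] or `NULL` to skip.
#' @param qpcr_reference reference gene for the qPCR stage (`NULL` skips).
#' @param seed master seed propagated to every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            probe_matrix = NULL, annotation = NULL,
                            ct_table = NULL, simulate = NULL,
                            floor = 1,
                            sam = sam_config(),
                            contrasts = NULL,
                            enrichment = NULL,
                            qpcr_reference = "Gapdh",
                            seed = 1L) {
  if (is.null(simulate)) {
    for (p in c(probe_matrix, annotation))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ", p, call. = FALSE)
  }
  structure(list(output_dir = output_dir, probe_matrix = probe_matrix,
                 annotation = annotation, ct_table = ct_table,
                 simulate = simulate, floor = floor, sam = sam,
                 contrasts = contrasts, enrichment = enrichment,
                 qpcr_reference = qpcr_reference, seed = as.integer(seed)),
            class = "pipeline_config")
}

derive_contrasts <- function(ann) {
  out <- list()
  for (tis in unique(ann$tissue)) for (tp in unique(ann$timepoint)) {
    tr <- unique(ann$treatment[ann$tissue == tis & ann$timepoint == tp])
    if ("control" %in% tr)
      for (t2 in setdiff(tr, "control"))
        out[[length(out) + 1L]] <- list(tissue = tis, timepoint = tp,
                                        treatment_a = "control",
                                        treatment_b = t2)
    if (all(c("EIH", "AMPH") %in% tr))
      out[[length(out) + 1L]] <- list(tissue = tis, timepoint = tp,
                                      treatment_a = "EIH",
                                      treatment_b = "AMPH")
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, then preprocessing, SAM differential
#' expression per contrast, enrichment calling and the qPCR stage, writing
#' every stage's table as TSV into the output directory plus a JSON run
#' manifest (tool version, config hash, input checksums, per-stage row
#' counts). With a fixed seed and identical inputs the outputs are
#' byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (written to stderr).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  counts <- list()

  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic dataset")
    sim <- generate_array_dataset(config$simulate)
    pm <- sim$probe_matrix
    ann <- sim$annotation
    write_probe_matrix(pm, file.path(config$output_dir, "probe_matrix.tsv"))
    write_annotation(ann, file.path(config$output_dir, "annotation.tsv"))
    truth_df <- rbind(
      if (nrow(sim$truth$de_genes))
        data.frame(gene = sim$truth$de_genes$gene, role = "de",
                   tissue = config$simulate$de_tissue,
                   contrast = sim$truth$de_genes$contrast,
                   effect = sim$truth$de_genes$sign *
                     config$simulate$de_log2_effect),
      do.call(rbind, lapply(names(sim$truth$enriched_genes), function(t)
        if (length(sim$truth$enriched_genes[[t]]))
          data.frame(gene = sim$truth$enriched_genes[[t]],
                     role = "enriched", tissue = t, contrast = NA,
                     effect = config$simulate$enrichment_log2_effect))),
      if (length(sim$truth$blood_genes))
        data.frame(gene = sim$truth$blood_genes, role = "blood",
                   tissue = "blood", contrast = NA,
                   effect = config$simulate$blood_log2_effect))
    if (!is.null(truth_df))
      write_tsv(truth_df, file.path(config$output_dir, "ground_truth.tsv"))
    ct <- if (!is.null(config$qpcr_reference))
      generate_ct_table(config$simulate) else NULL
  } else {
    pm <- read_probe_matrix(config$probe_matrix)
    ann <- read_annotation(config$annotation)
    ct <- if (!is.null(config$ct_table)) read_ct_table(config$ct_table)
  }
  bad <- setdiff(ann$sample_id, colnames(pm$foreground))
  if (length(bad))
    stop("annotation lists samples absent from the probe matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  counts$probes <- nrow(pm$foreground)
  counts$samples <- nrow(ann)

  say("stage preprocess: %d probes x %d samples", nrow(pm$foreground),
      ncol(pm$foreground))
  gm <- preprocess_probes(pm, floor = config$floor)
  write_gene_matrix(gm, file.path(config$output_dir, "gene_matrix.tsv"))
  counts$features <- nrow(gm$values)

  contrasts <- config$contrasts
  if (is.null(contrasts)) contrasts <- derive_contrasts(ann)
  deg_all <- list()
  for (ctr in contrasts) {
    tag <- sprintf("%s_%s_%s_vs_%s", ctr$tissue, ctr$timepoint,
                   ctr$treatment_b, ctr$treatment_a)
    say("stage sam: %s", tag)
    res <- run_sam(gm, ann,
                   group_a = list(tissue = ctr$tissue,
                                  treatment = ctr$treatment_a,
                                  timepoint = ctr$timepoint),
                   group_b = list(tissue = ctr$tissue,
                                  treatment = ctr$treatment_b,
                                  timepoint = ctr$timepoint),
                   config = config$sam)
    deg <- apply_deg_filters(res)
    deg_all[[tag]] <- deg
    write_tsv(data.frame(feature_id = res$features$feature_id,
                         gene_symbol = res$features$gene_symbol,
                         d = res$d, s = res$s,
                         rank = rank(res$d, ties.method = "first"),
                         dbar = res$dbar[rank(res$d,
                                              ties.method = "first")]),
              file.path(config$output_dir, paste0("sam_", tag, ".tsv")))
    write_tsv(res$delta_table,
              file.path(config$output_dir, paste0("sam_delta_", tag,
                                                  ".tsv")))
    write_tsv(deg, file.path(config$output_dir, paste0("deg_", tag,
                                                       ".tsv")))
    counts[[paste0("deg_", tag)]] <- nrow(deg)
  }

  if (!is.null(config$enrichment)) {
    ec <- config$enrichment
    say("stage enrich: %s vs %s", ec$target_tissue,
        paste(ec$reference_tissues, collapse = "+"))
    tissues <- c(ec$target_tissue, ec$reference_tissues, ec$blood_tissue)
    means <- sapply(tissues, function(t)
      gene_level_means(gm, ann, tissue = t))
    enr <- call_enrichment(means, ec)
    write_tsv(enr, file.path(config$output_dir, "enrichment.tsv"))
    counts$enriched <- sum(enr$enriched)
  }

  if (!is.null(ct) && !is.null(config$qpcr_reference)) {
    say("stage qpcr: %d Ct rows", nrow(ct))
    rel <- qpcr_relative(ct, reference = config$qpcr_reference)
    qs <- qpcr_summary(rel, reference = config$qpcr_reference)
    write_tsv(rel, file.path(config$output_dir, "qpcr_relative.tsv"))
    write_tsv(qs$summary, file.path(config$output_dir,
                                    "qpcr_summary.tsv"))
    write_tsv(qs$tests, file.path(config$output_dir, "qpcr_tests.tsv"))
    counts$qpcr_rows <- nrow(qs$summary)
  }

  manifest <- list(
    tool = "tissuesam",
    version = as.character(utils::packageVersion("tissuesam")),
    config_hash = config_hash(config),
    input_checksums = input_checksums(config),
    row_counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d stages, outputs in %s", length(counts), config$output_dir)
  invisible(manifest)
}

#' Gene-level raw-scale control means for enrichment
#'
#' Deduplicates a normalized gene matrix to one value per gene symbol
#' (averaging that gene's features) and returns raw-scale control-condition
#' means for one tissue.
#'
#' @param gm a normalized [gene_matrix()].
#' @param ann sample annotation.
#' @param tissue tissue label.
#' @param treatment treatment label (default `"control"`; blood arrays are
#'   control-only so the default applies there too).
#' @return named numeric vector over gene symbols.
#' @export
gene_level_means <- function(gm, ann, tissue, treatment = "control") {
  m <- back_transform_means(gm, ann,
                            list(tissue = tissue, treatment = treatment))
  v <- tapply(m, gm$features$gene_symbol, mean)
  genes <- unique(gm$features$gene_symbol)
  out <- as.numeric(v[genes])
  names(out) <- genes
  out
}

config_hash <- function(config) {
  ## canonical JSON of the analysis-relevant config -> md5; the output
  ## location does not change results, so it is excluded from the hash
  plain <- unclass(config)
  plain$output_dir <- NULL
  plain <- rapply(plain, function(x)
    if (is.function(x)) NULL else x, how = "replace")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

input_checksums <- function(config) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  config[c("probe_matrix", "annotation", "ct_table")])
  if (!length(paths)) return(list())
  sums <- tools::md5sum(unlist(paths))
  as.list(sums)
}
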