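#' Simulation configuration for synthetic array and qPCR data
#'
#' Builds a validated configuration describing a synthetic one-color
#' oligo-array study: four brain tissues (meninges/associated vasculature,
#' choroid plexus, striatum, parietal cortex) sampled under control,
#' hyperthermia (EIH) and amphetamine (AMPH) conditions at 3 hr and 1 day,
#' with multi-probe genes, log-normal intensities and optional planted
#' differential-expression, tissue-enrichment and blood-contaminant signals.
#'
#' Intensities are log-normal on the log2 scale: each gene draws a baseline
#' log2 mean, each probe a fixed additive log2 offset, each array an additive
#' log2 bias, and each measurement independent log2 noise. Spot background is
#' a normal draw truncated at zero, treated as a fixed per-spot property.
#'
#' @param n_genes number of genes on the array.
#' @param probes_per_gene_distribution named numeric vector of probabilities
#'   over probe counts; names must be integers in 1..7 and probabilities must
#'   sum to 1.
#' @param tissues character vector of tissue labels.
#' @param groups list of `c(treatment, timepoint)` pairs defining the study
#'   cells present in every tissue.
#' @param n_samples_per_cell arrays per tissue-by-group cell.
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of per-gene
#'   baseline log2 intensity.
#' @param probe_offset_sd SD of the fixed per-probe additive log2 offset.
#' @param array_noise_sd per-measurement log2 noise SD.
#' @param array_scale_sd per-array additive log2 bias SD (multiplicative on
#'   the raw scale).
#' @param background_mean,background_sd spot background distribution in raw
#'   fluorescence units (normal truncated at 0).
#' @param n_de_genes number of genes given a treatment effect.
#' @param de_log2_effect absolute log2 effect size for planted DE genes
#'   (2 means a 4-fold change); each gene is randomly up or down.
#' @param de_tissue tissue in which treatment effects are planted.
#' @param n_enriched_genes_per_tissue genes planted as enriched in each
#'   tissue relative to all others.
#' @param enrichment_log2_effect log2 enrichment effect; must exceed
#'   `log2(15)` for the default 15-fold caller to recover planted genes.
#' @param n_blood_genes genes elevated only in a pseudo-tissue "blood",
#'   generated (control condition only) whenever this is positive.
#' @param blood_log2_effect log2 elevation of blood genes in blood; must
#'   exceed `log2(5)` to trigger the blood-exclusion rule.
#' @param pooling_factor number of animals pooled per RNA aliquot for the
#'   choroid plexus; modeled as dividing measurement noise SD by
#'   `sqrt(pooling_factor)` in that tissue.
#' @param qpcr_reference reference gene label for simulated Ct tables.
#' @param ct_reference_mean mean reference-gene Ct (cycles).
#' @param ct_noise_sd per-replicate Ct noise SD (cycles).
#' @param n_ct_replicates technical qPCR replicates per sample.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       probes_per_gene_distribution = c(
                         "1" = 0.35, "2" = 0.25, "3" = 0.15,
                         "4" = 0.12, "5" = 0.07, "6" = 0.04, "7" = 0.02),
                       tissues = c("MAV", "choroid_plexus", "striatum",
                                   "parietal_cortex"),
                       groups = list(c("control", "3hr"),
                                     c("EIH", "3hr"),
                                     c("AMPH", "3hr"),
                                     c("EIH", "1day"),
                                     c("AMPH", "1day")),
                       n_samples_per_cell = 4,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       probe_offset_sd = 0.5,
                       array_noise_sd = 0.25,
                       array_scale_sd = 0.1,
                       background_mean = 50,
                       background_sd = 10,
                       n_de_genes = 0,
                       de_log2_effect = 2,
                       de_tissue = tissues[1],
                       n_enriched_genes_per_tissue = 0,
                       enrichment_log2_effect = 4,
                       n_blood_genes = 0,
                       blood_log2_effect = 3,
                       pooling_factor = 1,
                       qpcr_reference = "Gapdh",
                       ct_reference_mean = 20,
                       ct_noise_sd = 0.15,
                       n_ct_replicates = 2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    probes_per_gene_distribution = probes_per_gene_distribution,
    tissues = as.character(tissues),
    groups = groups,
    n_samples_per_cell = as.integer(n_samples_per_cell),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    probe_offset_sd = probe_offset_sd,
    array_noise_sd = array_noise_sd,
    array_scale_sd = array_scale_sd,
    background_mean = background_mean,
    background_sd = background_sd,
    n_de_genes = as.integer(n_de_genes),
    de_log2_effect = de_log2_effect,
    de_tissue = de_tissue,
    n_enriched_genes_per_tissue = as.integer(n_enriched_genes_per_tissue),
    enrichment_log2_effect = enrichment_log2_effect,
    n_blood_genes = as.integer(n_blood_genes),
    blood_log2_effect = blood_log2_effect,
    pooling_factor = pooling_factor,
    qpcr_reference = qpcr_reference,
    ct_reference_mean = ct_reference_mean,
    ct_noise_sd = ct_noise_sd,
    n_ct_replicates = as.integer(n_ct_replicates),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$probes_per_gene_distribution
  if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p)))))
    stop("probes_per_gene_distribution: names must be integer probe counts",
         call. = FALSE)
  ks <- as.integer(names(p))
  if (any(ks < 1L | ks > 7L))
    stop("probes_per_gene_distribution: support must lie in 1..7",
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("probes_per_gene_distribution: probabilities must sum to 1",
         call. = FALSE)
  if (any(p < 0))
    stop("probes_per_gene_distribution: probabilities must be >= 0",
         call. = FALSE)
  for (fld in c("n_genes", "n_samples_per_cell", "n_de_genes",
                "n_enriched_genes_per_tissue", "n_blood_genes",
                "n_ct_replicates"))
    if (is.na(cfg[[fld]]) || cfg[[fld]] < 0L)
      stop(fld, ": must be a non-negative count", call. = FALSE)
  for (fld in c("baseline_log2_sd", "probe_offset_sd", "array_noise_sd",
                "array_scale_sd", "background_sd", "ct_noise_sd"))
    if (cfg[[fld]] < 0)
      stop(fld, ": must be >= 0", call. = FALSE)
  if (cfg$n_samples_per_cell < 1L)
    stop("n_samples_per_cell: must be at least 1", call. = FALSE)
  planted <- cfg$n_de_genes +
    cfg$n_enriched_genes_per_tissue * length(cfg$tissues) +
    cfg$n_blood_genes
  if (planted > cfg$n_genes)
    stop("n_genes: too small to host all planted gene roles (",
         planted, " needed)", call. = FALSE)
  if (!cfg$de_tissue %in% cfg$tissues)
    stop("de_tissue: not among the configured tissues", call. = FALSE)
  if (cfg$pooling_factor < 1)
    stop("pooling_factor: must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic probe-level array dataset with ground truth
#'
#' Draws a complete probe-level dataset under `config`: per-gene baseline
#' log2 means, per-probe offsets, per-array biases and measurement noise,
#' with planted treatment effects (in `de_tissue`, all non-control groups),
#' tissue-enrichment effects, and blood-contaminant genes elevated in a
#' pseudo-tissue `"blood"` (control arrays only). Foreground equals the spot
#' background plus `2^` the log2 signal, so background subtraction recovers
#' the signal exactly.
#'
#' @param config a [sim_config()] object.
#' @return a list with components `probe_matrix` (a [probe_matrix()]),
#'   `annotation` (a sample annotation `data.frame` with columns
#'   `sample_id`, `tissue`, `treatment`, `timepoint`, `slide_id`) and
#'   `truth` (a `ground_truth` list with `de_genes` data.frame
#'   (gene, contrast, sign), `enriched_genes` per-tissue list, and
#'   `blood_genes`).
#' @export
generate_array_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))

  ## planted roles occupy disjoint leading blocks
  cursor <- 0L
  take <- function(n) {
    idx <- if (n > 0L) (cursor + 1L):(cursor + n) else integer(0)
    cursor <<- cursor + n
    idx
  }
  de_idx <- take(cfg$n_de_genes)
  enr_idx <- lapply(cfg$tissues, function(t)
    take(cfg$n_enriched_genes_per_tissue))
  names(enr_idx) <- cfg$tissues
  blood_idx <- take(cfg$n_blood_genes)

  gene_mean <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                            cfg$baseline_log2_sd)
  ks <- as.integer(names(cfg$probes_per_gene_distribution))
  k_per_gene <- sample(ks, cfg$n_genes, replace = TRUE,
                       prob = cfg$probes_per_gene_distribution)
  gidx <- rep.int(seq_len(cfg$n_genes), k_per_gene)
  probe_id <- paste0(genes[gidx], "_p",
                     sequence(k_per_gene))
  np <- length(probe_id)
  probe_offset <- stats::rnorm(np, 0, cfg$probe_offset_sd)
  de_sign <- sample(c(1, -1), cfg$n_de_genes, replace = TRUE)

  ## sample layout: every tissue x group cell, plus control-only blood arrays
  tissues_out <- cfg$tissues
  cells <- expand.grid(cell = seq_along(cfg$groups),
                       tissue = tissues_out,
                       stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    g <- cfg$groups[[cells$cell[i]]]
    data.frame(tissue = cells$tissue[i], treatment = g[1], timepoint = g[2],
               stringsAsFactors = FALSE)
  }))
  ann <- ann[rep(seq_len(nrow(ann)), each = cfg$n_samples_per_cell), ]
  if (cfg$n_blood_genes > 0L) {
    ctrl <- Filter(function(g) g[1] == "control", cfg$groups)
    tp <- if (length(ctrl)) ctrl[[1]][2] else cfg$groups[[1]][2]
    blood_ann <- data.frame(tissue = "blood", treatment = "control",
                            timepoint = tp, stringsAsFactors = FALSE)
    blood_ann <- blood_ann[rep(1L, cfg$n_samples_per_cell), ]
    ann <- rbind(ann, blood_ann)
  }
  rep_idx <- stats::ave(seq_len(nrow(ann)),
                        ann$tissue, ann$treatment, ann$timepoint,
                        FUN = seq_along)
  ann$sample_id <- sprintf("%s_%s_%s_r%d", ann$tissue, ann$treatment,
                           ann$timepoint, rep_idx)
  ns <- nrow(ann)
  ann$slide_id <- sprintf("slide%03d", (seq_len(ns) - 1L) %/% 4L + 1L)
  rownames(ann) <- NULL
  ann <- ann[, c("sample_id", "tissue", "treatment", "timepoint", "slide_id")]

  ## per-gene x tissue additive log2 effects (enrichment, blood)
  all_tissues <- unique(ann$tissue)
  eff <- matrix(0, cfg$n_genes, length(all_tissues),
                dimnames = list(NULL, all_tissues))
  for (t in cfg$tissues)
    eff[enr_idx[[t]], t] <- eff[enr_idx[[t]], t] + cfg$enrichment_log2_effect
  if (cfg$n_blood_genes > 0L)
    eff[blood_idx, "blood"] <- eff[blood_idx, "blood"] + cfg$blood_log2_effect

  bg_probe <- pmax(stats::rnorm(np, cfg$background_mean, cfg$background_sd), 0)
  array_bias <- stats::rnorm(ns, 0, cfg$array_scale_sd)
  noise_sd <- rep(cfg$array_noise_sd, ns)
  noise_sd[ann$tissue == "choroid_plexus"] <-
    cfg$array_noise_sd / sqrt(cfg$pooling_factor)
  noise <- matrix(stats::rnorm(np * ns), np, ns) *
    rep(noise_sd, each = np)

  mu <- matrix(gene_mean[gidx] + probe_offset, np, ns)
  mu <- mu + eff[gidx, ann$tissue, drop = FALSE]
  treated <- ann$tissue == cfg$de_tissue & ann$treatment != "control"
  if (cfg$n_de_genes > 0L && any(treated)) {
    de_col <- numeric(cfg$n_genes)
    de_col[de_idx] <- de_sign * cfg$de_log2_effect
    mu[, treated] <- mu[, treated] + de_col[gidx]
  }
  mu <- mu + rep(array_bias, each = np) + noise

  bg <- matrix(bg_probe, np, ns)
  fg <- bg + 2^mu
  dimnames(fg) <- dimnames(bg) <- list(probe_id, ann$sample_id)

  truth <- list(
    de_genes = do.call(rbind, c(list(
      data.frame(gene = character(0), contrast = character(0),
                 sign = numeric(0))),
      lapply(Filter(function(g) g[1] != "control", cfg$groups), function(g) {
        if (cfg$n_de_genes == 0L) return(NULL)
        data.frame(gene = genes[de_idx],
                   contrast = paste(g[1], g[2], sep = "_"),
                   sign = de_sign, stringsAsFactors = FALSE)
      }))),
    enriched_genes = lapply(enr_idx, function(i) genes[i]),
    blood_genes = genes[blood_idx]
  )
  class(truth) <- "ground_truth"

  pm <- probe_matrix(
    probes = data.frame(probe_id = probe_id, gene_symbol = genes[gidx],
                        stringsAsFactors = FALSE),
    foreground = fg, background = bg)

  list(probe_matrix = pm, annotation = ann, truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Simulates threshold-cycle (Ct) values for a small gene panel relative to
#' a reference gene: each sample's gene Ct is the reference Ct minus
#' `log2(relative abundance)` plus replicate noise, so the
#' `2^-deltaCt * 100` transform recovers the simulated percent-of-reference
#' abundance. Nonexpressed genes (abundance `NA` or 0) draw Ct values above
#' the 35-cycle limit of quantification.
#'
#' @param config a [sim_config()] object (uses the qPCR fields, `tissues`,
#'   `groups`, `n_samples_per_cell` and `seed`).
#' @param abundance named list or vector giving each panel gene's relative
#'   abundance as a fraction of the reference gene (1 = 100%). An element
#'   may be a single number, or a named vector keyed by
#'   `"<treatment>_<timepoint>"` to vary by group. `NA` or 0 marks a gene
#'   nonexpressed. The reference gene itself is always included at 1.
#' @param tissues tissues to simulate; defaults to `config$tissues`.
#' @return a `data.frame` Ct table with columns `sample_id`, `tissue`,
#'   `treatment`, `timepoint`, `gene_symbol`, `replicate`, `ct`.
#' @export
generate_ct_table <- function(config,
                              abundance = list(g_equal = 1,
                                               g_low = 2^-10,
                                               g_ne = NA_real_),
                              tissues = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$qpcr_reference) || !nzchar(config$qpcr_reference))
    stop("qpcr_reference: a reference gene label is required", call. = FALSE)
  if (is.null(names(abundance)) || any(!nzchar(names(abundance))))
    stop("abundance: must be a named list of panel genes", call. = FALSE)
  set.seed(config$seed)
  if (is.null(tissues)) tissues <- config$tissues
  genes <- c(config$qpcr_reference, names(abundance))

  rows <- list()
  for (tis in tissues) for (g in config$groups) {
    glab <- paste(g[1], g[2], sep = "_")
    for (i in seq_len(config$n_samples_per_cell)) {
      sid <- sprintf("%s_%s_r%d", tis, glab, i)
      for (gene in genes) {
        if (gene == config$qpcr_reference) {
          rel <- 1
        } else {
          a <- abundance[[gene]]
          rel <- if (length(a) > 1L || !is.null(names(a))) {
            if (glab %in% names(a)) unname(a[[glab]]) else unname(a[[1L]])
          } else a
        }
        if (is.na(rel) || rel <= 0) {
          ct <- stats::runif(config$n_ct_replicates, 35.5, 40)
        } else {
          ct_true <- config$ct_reference_mean - log2(rel)
          ct <- ct_true + stats::rnorm(config$n_ct_replicates, 0,
                                       config$ct_noise_sd)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, tissue = tis, treatment = g[1], timepoint = g[2],
          gene_symbol = gene, replicate = seq_len(config$n_ct_replicates),
          ct = ct, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
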