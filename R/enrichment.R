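#' Configuration for cross-tissue enrichment calling
#'
#' @param target_tissue tissue whose enriched genes are sought.
#' @param reference_tissues tissues the target is compared against (the
#'   neuronal-rich striatum and parietal cortex by default).
#' @param fold_threshold minimum fold excess over *both* references for a
#'   gene to be called enriched (15 by default; 10 as a common variant).
#' @param blood_tissue label of the blood expression column, or `NULL` to
#'   skip blood exclusion.
#' @param blood_fold_threshold genes whose blood mean is at least this many
#'   fold above the target-tissue mean are excluded as likely residual-blood
#'   signal (5 by default).
#' @param bins decreasing fold thresholds defining the report bins
#'   (default `c(50, 30, 15)` giving ">50", "30-50", "15-30").
#' @return an object of class `enrichment_config`.
#' @export
enrichment_config <- function(target_tissue = "choroid_plexus",
                              reference_tissues = c("striatum",
                                                    "parietal_cortex"),
                              fold_threshold = 15,
                              blood_tissue = NULL,
                              blood_fold_threshold = 5,
                              bins = c(50, 30, 15)) {
  if (fold_threshold <= 1)
    stop("fold_threshold must exceed 1", call. = FALSE)
  if (is.unsorted(rev(bins), strictly = TRUE))
    stop("bins must be strictly decreasing", call. = FALSE)
  structure(list(target_tissue = target_tissue,
                 reference_tissues = reference_tissues,
                 fold_threshold = fold_threshold,
                 blood_tissue = blood_tissue,
                 blood_fold_threshold = blood_fold_threshold,
                 bins = bins),
            class = "enrichment_config")
}

fold_bin_labels <- function(bins) {
  n <- length(bins)
  c(paste0(">", bins[1L]),
    if (n > 1L) paste0(bins[-1L], "-", bins[-n]))
}

assign_fold_bin <- function(fold, bins) {
  labels <- fold_bin_labels(bins)
  out <- rep(NA_character_, length(fold))
  out[fold > bins[1L]] <- labels[1L]
  if (length(bins) > 1L)
    for (i in 2:length(bins)) {
      ## boundary genes (fold equal to an upper edge) fall in the lower bin
      sel <- fold >= bins[i] & fold <= bins[i - 1L] & is.na(out)
      out[sel] <- labels[i]
    }
  out
}

#' Call tissue-enriched genes from control-condition means
#'
#' For each gene the fold excess of the target tissue over each reference is
#' computed and the minimum taken (i.e. the fold versus the more highly
#' expressing reference). A gene is enriched when that minimum fold reaches
#' `fold_threshold` and the gene is not blood-excluded: a gene whose blood
#' mean is at least `blood_fold_threshold` times its target-tissue mean is
#' flagged as probable residual-blood contamination and never called.
#'
#' @param means numeric matrix or data.frame of raw-scale control means,
#'   genes in rows (rownames = gene symbols), tissues in columns.
#' @param config an [enrichment_config()].
#' @return `data.frame` with one row per gene: `gene_symbol`, `mean_target`,
#'   one `mean_<ref>` column per reference, `min_fold`, `blood_fold`,
#'   `excluded_by_blood`, `enriched`, `bin`.
#' @export
call_enrichment <- function(means, config = enrichment_config()) {
  stopifnot(inherits(config, "enrichment_config"))
  means <- as.matrix(means)
  need <- c(config$target_tissue, config$reference_tissues,
            config$blood_tissue)
  missing <- setdiff(need, colnames(means))
  if (length(missing))
    stop("means lack tissue column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  target <- means[, config$target_tissue]
  refs <- means[, config$reference_tissues, drop = FALSE]
  if (any(refs == 0)) {
    warning("zero reference mean: fold set to Inf for affected genes")
  }
  folds <- target / refs
  min_fold <- apply(folds, 1L, min)

  if (!is.null(config$blood_tissue)) {
    blood_fold <- means[, config$blood_tissue] / target
    excluded <- blood_fold >= config$blood_fold_threshold
  } else {
    blood_fold <- rep(NA_real_, length(target))
    excluded <- rep(FALSE, length(target))
  }
  enriched <- min_fold >= config$fold_threshold & !excluded
  out <- data.frame(
    gene_symbol = if (!is.null(rownames(means))) rownames(means)
                  else sprintf("gene%d", seq_along(target)),
    mean_target = target, stringsAsFactors = FALSE)
  for (r in config$reference_tissues) out[[paste0("mean_", r)]] <- means[, r]
  out$min_fold <- min_fold
  out$blood_fold <- blood_fold
  out$excluded_by_blood <- excluded
  out$enriched <- enriched
  out$bin <- ifelse(enriched, assign_fold_bin(min_fold, config$bins),
                    NA_character_)
  rownames(out) <- NULL
  out
}

#' Directional overlap between two gene sets
#'
#' Fraction of the first set's genes found in the second.
#'
#' @param set_a,set_b character vectors of gene symbols; `set_a` non-empty.
#' @return `|set_a intersect set_b| / |set_a|`.
#' @export
overlap_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a)) stop("set_a must be non-empty", call. = FALSE)
  length(intersect(set_a, set_b)) / length(set_a)
}

#' Expected number of high-expression genes in a DEG list
#'
#' Under the null of no association, a differentially expressed gene list of
#' size `n_deg` is expected to contain `round(p * n_deg)` genes from a
#' high-expression class comprising `n_high` of `n_total` array genes.
#'
#' @param n_high number of high-expression (e.g. 15-fold enriched) genes.
#' @param n_total total genes on the array.
#' @param n_deg size of the differentially-expressed list.
#' @return expected count, rounded to the nearest integer.
#' @export
expected_deg_count <- function(n_high, n_total, n_deg) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  round(n_high / n_total * n_deg)
}

#' Expected versus observed enrichment counts per contrast
#'
#' Compares, for each differential-expression contrast, how many genes of a
#' high-expression (tissue-enriched) class would be expected in the DEG list
#' by proportion alone with how many are observed.
#'
#' @param enriched_genes character vector of enriched gene symbols, or a
#'   bare count when only totals are available.
#' @param deg_lists named list; each element a character vector of DEG
#'   symbols (deduplicated), or a bare count (observed then `NA`).
#' @param n_total total number of genes on the array.
#' @param binomial_p also compute, per contrast, the binomial tail
#'   probability `P(X >= observed)` for `X ~ Binom(n_deg, p)` (off by
#'   default: the comparison is reported as raw counts).
#' @return list with `n_high`, `n_total`, `proportion`, and `per_contrast`,
#'   a `data.frame` (`contrast`, `n_deg`, `expected`, `observed`, and
#'   `p_binomial` when requested).
#' @export
expected_observed_counts <- function(enriched_genes, deg_lists, n_total,
                                     binomial_p = FALSE) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  n_high <- if (is.numeric(enriched_genes) && length(enriched_genes) == 1L)
    enriched_genes else length(unique(enriched_genes))
  p <- n_high / n_total
  per <- do.call(rbind, lapply(names(deg_lists), function(nm) {
    dl <- deg_lists[[nm]]
    if (is.numeric(dl) && length(dl) == 1L) {
      n_deg <- dl; obs <- NA_integer_
    } else {
      dl <- unique(dl)
      n_deg <- length(dl)
      obs <- if (is.character(enriched_genes))
        length(intersect(dl, enriched_genes)) else NA_integer_
    }
    row <- data.frame(contrast = nm, n_deg = n_deg,
                      expected = expected_deg_count(n_high, n_total, n_deg),
                      observed = obs, stringsAsFactors = FALSE)
    if (binomial_p)
      row$p_binomial <- if (is.na(obs)) NA_real_ else
        stats::pbinom(obs - 1L, n_deg, n_high / n_total,
                      lower.tail = FALSE)
    row
  }))
  list(n_high = n_high, n_total = n_total, proportion = p,
       per_contrast = per)
}

#' Correlation of control expression between two tissues
#'
#' Pearson correlation of per-gene control means, computed on the log2
#' scale by default (set `log2 = FALSE` for the raw scale).
#'
#' @param means_a,means_b aligned numeric vectors of per-gene raw-scale
#'   control means for the two tissues (at least 3 genes).
#' @param log2 correlate log2-transformed means.
#' @return the correlation coefficient; `NA` with a warning when either
#'   vector has zero variance.
#' @export
control_correlation <- function(means_a, means_b, log2 = TRUE) {
  if (length(means_a) != length(means_b) || length(means_a) < 3L)
    stop("need aligned vectors of at least 3 genes", call. = FALSE)
  if (log2) {
    means_a <- base::log2(means_a)
    means_b <- base::log2(means_b)
  }
  if (stats::sd(means_a) == 0 || stats::sd(means_b) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(means_a, means_b)
}
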