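#' Relative quantity from threshold cycles
#'
#' Expression of a gene as a percentage of the reference gene:
#' `2^-(ct_gene - ct_ref) * 100`. Equal cycles give exactly 100; each cycle
#' earlier doubles the relative quantity.
#'
#' @param ct_gene,ct_ref threshold cycles of the gene of interest and the
#'   endogenous reference (e.g. Gapdh) in the same sample.
#' @return relative quantity in percent of the reference.
#' @export
relative_quantity <- function(ct_gene, ct_ref) {
  if (anyNA(ct_ref))
    stop("missing reference Ct", call. = FALSE)
  2^-(ct_gene - ct_ref) * 100
}

#' Expression call from a Ct value
#'
#' Genes with Ct above 35 cycles are below the limit of quantification and
#' considered not expressed; Ct equal to 35 still counts as expressed.
#'
#' @param ct threshold cycle(s).
#' @return logical: `TRUE` when expressed.
#' @export
censor_ct <- function(ct) {
  ct <= 35
}

#' Reported fold between two group mean relative quantities
#'
#' The ratio of group means, rounded to two decimals for reporting. For the
#' 3 hr design the comparator is the control group; for the 1 day design
#' (which has no control arm) the comparator is the EIH group.
#'
#' @param mean_treat,mean_comp group means of relative quantities;
#'   `mean_comp` must be positive.
#' @return the fold, rounded to 2 decimal places.
#' @export
group_fold <- function(mean_treat, mean_comp) {
  if (any(is.na(mean_comp)) || any(mean_comp <= 0))
    stop("comparator mean must be positive", call. = FALSE)
  round(mean_treat / mean_comp, 2)
}

#' Kruskal-Wallis test with Dunn's pairwise follow-up
#'
#' Omnibus Kruskal-Wallis test (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's rank-based pairwise z tests with a family-wise
#' p-value adjustment (Holm by default, Bonferroni available).
#'
#' @param values numeric vector of (relative-quantity) observations.
#' @param groups grouping factor/character vector, at least 2 levels.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return list with `H`, `df`, `p_value` (omnibus) and `pairwise`, a
#'   `data.frame` (`group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`).
#' @export
kw_dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  kw <- stats::kruskal.test(values, factor(groups, levels = lev))

  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)[lev]
  n_g <- tapply(r, groups, length)[lev]
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[[p[1L]]] + 1 / n_g[[p[2L]]]))
    z <- if (se > 0) (mean_rank[[p[1L]]] - mean_rank[[p[2L]]]) / se else 0
    data.frame(group_a = p[1L], group_b = p[2L], z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = p_adjust)
  H <- unname(kw$statistic)
  if (!is.finite(H)) H <- 0
  list(H = H, df = unname(kw$parameter),
       p_value = if (is.finite(kw$p.value)) kw$p.value else 1,
       pairwise = pw)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when sample sizes allow and no ties are present (the default
#' behavior of [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `U` and `p_value` (1 when all values are tied).
#' @export
mw_u_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-sample relative quantities from a Ct table
#'
#' Technical replicates are averaged on the Ct scale per (sample, gene);
#' the averaged Ct is censored at 35 cycles; expressed genes get
#' `2^-deltaCt * 100` relative to the same sample's reference-gene Ct.
#'
#' @param ct_table `data.frame` with columns `sample_id`, `tissue`,
#'   `treatment`, `timepoint`, `gene_symbol`, `replicate`, `ct`.
#' @param reference reference gene symbol (default `"Gapdh"`).
#' @return `data.frame` with one row per (sample, gene): annotation columns
#'   plus `ct_mean`, `expressed`, `relative_quantity` (`NA` when censored).
#' @export
qpcr_relative <- function(ct_table, reference = "Gapdh") {
  need <- c("sample_id", "tissue", "treatment", "timepoint",
            "gene_symbol", "ct")
  missing <- setdiff(need, names(ct_table))
  if (length(missing))
    stop("ct_table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive",
                                  call. = FALSE)
  agg <- stats::aggregate(
    ct ~ sample_id + tissue + treatment + timepoint + gene_symbol,
    data = ct_table, FUN = mean)
  names(agg)[names(agg) == "ct"] <- "ct_mean"
  ref <- agg[agg$gene_symbol == reference, c("sample_id", "ct_mean")]
  if (!nrow(ref))
    stop("reference gene '", reference, "' absent from ct_table",
         call. = FALSE)
  names(ref)[2L] <- "ct_ref"
  out <- merge(agg, ref, by = "sample_id", all.x = TRUE)
  if (anyNA(out$ct_ref))
    stop("missing reference Ct for sample(s): ",
         paste(unique(out$sample_id[is.na(out$ct_ref)]), collapse = ", "),
         call. = FALSE)
  out$expressed <- censor_ct(out$ct_mean)
  out$relative_quantity <- ifelse(out$expressed,
                                  relative_quantity(out$ct_mean, out$ct_ref),
                                  NA_real_)
  out[order(out$gene_symbol, out$tissue, out$treatment, out$timepoint,
            out$sample_id), ]
}

#' Group summaries, folds and tests for qPCR relative quantities
#'
#' Summarizes relative quantities per (gene, tissue, treatment, timepoint)
#' as mean and SD; attaches reported folds (3 hr groups versus 3 hr control,
#' 1 day AMPH versus 1 day EIH); and runs the 3 hr Kruskal-Wallis/Dunn test
#' across treatments and the 1 day Mann-Whitney U test per (gene, tissue).
#' Groups in which every sample is censored are reported as `"N.E."` (not
#' expressed); absent combinations as `"N.D."` (not determined).
#'
#' @param rel output of [qpcr_relative()].
#' @param reference reference gene symbol to drop from the report.
#' @param p_adjust pairwise adjustment method for the 3 hr test.
#' @return list with `summary` (a `data.frame`: gene, tissue, treatment,
#'   timepoint, n, n_expressed, mean, sd, fold, display) and `tests` (a
#'   `data.frame` per gene x tissue x timepoint with the test statistics).
#' @export
qpcr_summary <- function(rel, reference = "Gapdh", p_adjust = "holm") {
  rel <- rel[rel$gene_symbol != reference, , drop = FALSE]
  key <- interaction(rel$gene_symbol, rel$tissue, rel$treatment,
                     rel$timepoint, drop = TRUE)
  summ <- do.call(rbind, lapply(split(rel, key), function(gr) {
    rq <- gr$relative_quantity[gr$expressed]
    data.frame(gene_symbol = gr$gene_symbol[1L], tissue = gr$tissue[1L],
               treatment = gr$treatment[1L], timepoint = gr$timepoint[1L],
               n = nrow(gr), n_expressed = sum(gr$expressed),
               mean = if (length(rq)) mean(rq) else NA_real_,
               sd = if (length(rq) > 1L) stats::sd(rq) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  comparator <- function(gene, tissue, timepoint) {
    comp_treat <- if (timepoint == "1day") "EIH" else "control"
    i <- summ$gene_symbol == gene & summ$tissue == tissue &
      summ$timepoint == timepoint & summ$treatment == comp_treat
    if (any(i)) summ$mean[which(i)[1L]] else NA_real_
  }
  summ$fold <- NA_real_
  for (i in seq_len(nrow(summ))) {
    comp_treat <- if (summ$timepoint[i] == "1day") "EIH" else "control"
    if (summ$treatment[i] == comp_treat) next
    cm <- comparator(summ$gene_symbol[i], summ$tissue[i], summ$timepoint[i])
    if (!is.na(cm) && cm > 0 && !is.na(summ$mean[i]))
      summ$fold[i] <- group_fold(summ$mean[i], cm)
  }
  summ$display <- ifelse(summ$n_expressed == 0L, "N.E.",
                         sprintf("%.3g ± %.3g", summ$mean, summ$sd))

  tests <- list()
  for (gene in unique(rel$gene_symbol)) for (tis in unique(rel$tissue)) {
    sub <- rel[rel$gene_symbol == gene & rel$tissue == tis, , drop = FALSE]
    h3 <- sub[sub$timepoint != "1day" & sub$expressed, , drop = FALSE]
    if (nrow(h3) && length(unique(h3$treatment)) >= 2L) {
      kt <- kw_dunn_test(h3$relative_quantity, h3$treatment,
                         p_adjust = p_adjust)
      tests[[length(tests) + 1L]] <- data.frame(
        gene_symbol = gene, tissue = tis, timepoint = "3hr",
        test = "kruskal_wallis", statistic = kt$H, p_value = kt$p_value,
        min_pairwise_p = if (nrow(kt$pairwise))
          min(kt$pairwise$p_adjusted) else NA_real_,
        stringsAsFactors = FALSE)
    }
    d1 <- sub[sub$timepoint == "1day" & sub$expressed, , drop = FALSE]
    a <- d1$relative_quantity[d1$treatment == "AMPH"]
    e <- d1$relative_quantity[d1$treatment == "EIH"]
    if (length(a) && length(e)) {
      mt <- mw_u_test(a, e)
      tests[[length(tests) + 1L]] <- data.frame(
        gene_symbol = gene, tissue = tis, timepoint = "1day",
        test = "mann_whitney", statistic = mt$U, p_value = mt$p_value,
        min_pairwise_p = NA_real_, stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(gene_symbol = character(0), tissue = character(0),
               timepoint = character(0), test = character(0),
               statistic = numeric(0), p_value = numeric(0),
               min_pairwise_p = numeric(0))
  list(summary = summ, tests = tests)
}
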