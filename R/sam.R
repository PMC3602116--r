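#' Configuration for SAM-style differential expression
#'
#' @param target_fdr target false discovery rate for delta selection
#'   (0.10 for the 3 hr design, 0.20 for 1 day).
#' @param s0_strategy how the fudge factor s0 is chosen:
#'   `"tusher_cv_min"` minimizes the coefficient of variation of the
#'   moderated statistics across standard-error windows over a percentile
#'   candidate grid; `"fixed"` uses `s0_fixed`.
#' @param s0_fixed fixed fudge factor when `s0_strategy = "fixed"`.
#' @param max_permutations label permutations are enumerated exhaustively up
#'   to this count, and sampled (seeded) beyond it.
#' @param seed seed for sampled permutations.
#' @param intensity_min post-filter: at least one group's raw-scale mean
#'   must reach this intensity (150 raw units).
#' @param fc_min post-filter: the raw-scale fold change must exceed this in
#'   either direction (1.3).
#' @param false_stat summary of per-permutation false-call counts used in
#'   the FDR numerator: `"mean"` (the original SAM convention; default) or
#'   `"median"` (the later samr convention). The false-count distribution is
#'   strongly right-skewed, so the median collapses to zero whenever more
#'   than half the permutations place nothing beyond the cuts, which makes
#'   small spurious call sets look like FDR 0 on null data; the mean keeps
#'   the estimate honest there.
#' @param pi0 multiplier on the FDR numerator estimating the proportion of
#'   truly null features; 1 (off) by default, matching raw permutation FDR
#'   reporting.
#' @param n_deltas size of the delta grid for the FDR table.
#' @return an object of class `sam_config`.
#' @export
sam_config <- function(target_fdr = 0.10,
                       s0_strategy = c("tusher_cv_min", "fixed"),
                       s0_fixed = 0,
                       max_permutations = 10000L,
                       seed = 1L,
                       intensity_min = 150,
                       fc_min = 1.3,
                       false_stat = c("mean", "median"),
                       pi0 = 1,
                       n_deltas = 101L) {
  s0_strategy <- match.arg(s0_strategy)
  false_stat <- match.arg(false_stat)
  if (target_fdr <= 0 || target_fdr >= 1)
    stop("target_fdr must lie in (0, 1)", call. = FALSE)
  if (fc_min <= 1) stop("fc_min must exceed 1", call. = FALSE)
  if (s0_fixed < 0) stop("s0_fixed must be >= 0", call. = FALSE)
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  structure(list(target_fdr = target_fdr, s0_strategy = s0_strategy,
                 s0_fixed = s0_fixed,
                 max_permutations = as.integer(max_permutations),
                 seed = as.integer(seed), intensity_min = intensity_min,
                 fc_min = fc_min, false_stat = false_stat, pi0 = pi0,
                 n_deltas = as.integer(n_deltas)),
            class = "sam_config")
}

## pooled standard error and moderated statistic for a features x samples
## matrix split into two groups of columns
sam_statistics <- function(mat, idx_a, idx_b, s0 = 0, compute_d = TRUE) {
  na <- length(idx_a); nb <- length(idx_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  rss <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * rss / (na + nb - 2L))
  num <- mb - ma
  d <- NULL
  if (compute_d) {
    denom <- s + s0
    d <- ifelse(denom > 0, num / denom,
                ifelse(num == 0, 0, NA_real_))
    if (anyNA(d))
      stop("zero standard error with nonzero mean difference and s0 = 0",
           call. = FALSE)
  }
  list(d = d, s = s, numerator = num, mean_a = ma, mean_b = mb)
}

#' Moderated (SAM) t statistic for two groups
#'
#' `d = (mean_b - mean_a) / (s + s0)` with the pooled standard error
#' `s = sqrt((1/n_a + 1/n_b) * (SS_a + SS_b) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b numeric vectors of (log2) values, length >= 2 each.
#' @param s0 fudge factor added to the standard error.
#' @return list with elements `d` and `s`.
#' @export
sam_statistic <- function(group_a, group_b, s0 = 0) {
  res <- sam_statistics(rbind(c(group_a, group_b)),
                        seq_along(group_a),
                        length(group_a) + seq_along(group_b), s0 = s0)
  list(d = unname(res$d), s = unname(res$s))
}

#' Choose the SAM fudge factor s0
#'
#' `"tusher_cv_min"` evaluates candidate s0 values at the percentiles
#' 0, 5, ..., 100 of the standard-error distribution. For each candidate it
#' moderates the statistics, measures their spread (median absolute
#' deviation) within windows of the standard-error distribution, and picks
#' the candidate minimizing the coefficient of variation of those spreads;
#' ties go to the smaller s0. With a degenerate (constant) standard-error
#' distribution the smallest candidate is returned.
#'
#' @param numerators per-feature mean differences.
#' @param s per-feature pooled standard errors.
#' @param strategy `"tusher_cv_min"` or `"fixed"`.
#' @param s0_fixed value returned under `"fixed"`.
#' @return the chosen s0.
#' @export
choose_s0 <- function(numerators, s,
                      strategy = c("tusher_cv_min", "fixed"),
                      s0_fixed = 0) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") return(s0_fixed)
  if (!length(s)) stop("empty input", call. = FALSE)
  cand <- unique(as.numeric(stats::quantile(s, seq(0, 1, 0.05),
                                            names = FALSE)))
  cand <- sort(cand)
  ## a zero fudge factor is undefined for zero-variance features (ties at
  ## the background floor can produce them): restrict to positive s0 then
  if (any(s == 0)) {
    cand <- cand[cand > 0]
    if (!length(cand))
      stop("all pooled standard errors are zero", call. = FALSE)
  }
  breaks <- unique(stats::quantile(s, seq(0, 1, 0.05), names = FALSE))
  if (length(breaks) < 3L) return(cand[1L])
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- numerators / (s + s0)
    v <- as.numeric(tapply(d, win, stats::mad))
    v <- v[is.finite(v)]
    m <- mean(v)
    if (!length(v) || m == 0) Inf else stats::sd(v) / m
  }, numeric(1))
  cand[which.min(cv)]
}

#' Permutation null distribution of SAM order statistics
#'
#' Permutes the two-class labels, recomputes every feature's moderated
#' statistic (standard error re-estimated per permutation, same s0) and
#' sorts each permutation's statistics. When the number of distinct label
#' assignments is at most `max_permutations` all of them are enumerated
#' (e.g. choose(8, 4) = 70 for 4 vs 4); otherwise `max_permutations`
#' distinct assignments are sampled with the seeded generator. The expected
#' order statistics are the per-rank means over permutations.
#'
#' @param mat features x samples numeric matrix (log2 scale).
#' @param labels two-level factor/character vector over columns.
#' @param s0 fudge factor (held fixed across permutations).
#' @param max_permutations,seed see [sam_config()].
#' @return list with `perm_sorted` (features x permutations matrix of sorted
#'   statistics), `dbar` (expected order statistics, ascending),
#'   `n_permutations`, and `exhaustive` flag.
#' @export
permutation_null <- function(mat, labels, s0 = 0,
                             max_permutations = 10000L, seed = 1L) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly 2 levels",
                              call. = FALSE)
  n <- ncol(mat)
  na <- sum(labels == lev[1L])
  nb <- n - na
  if (na < 2L || nb < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  n_all <- choose(n, na)
  if (n_all <= max_permutations) {
    combos <- utils::combn(n, na, simplify = FALSE)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    combos <- list()
    while (length(combos) < max_permutations) {
      x <- sort(sample.int(n, na))
      key <- paste(x, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        combos[[length(combos) + 1L]] <- x
      }
    }
    exhaustive <- FALSE
  }
  perm_sorted <- vapply(combos, function(idx_a) {
    sort(sam_statistics(mat, idx_a, setdiff(seq_len(n), idx_a), s0 = s0)$d)
  }, numeric(nrow(mat)))
  if (is.null(dim(perm_sorted)))
    perm_sorted <- matrix(perm_sorted, nrow = nrow(mat))
  list(perm_sorted = perm_sorted, dbar = rowMeans(perm_sorted),
       n_permutations = length(combos), exhaustive = exhaustive)
}

#' Delta / FDR table from observed and permutation order statistics
#'
#' For each delta, the observed sorted statistics are compared with the
#' permutation-expected order statistics: scanning up from the origin, the
#' first rank at which the observed exceeds the expected by more than delta
#' yields an upper cut candidate; symmetrically below for the lower one. The
#' final cut values are symmetric, at plus/minus the smaller candidate
#' magnitude, and features beyond them are called. The estimated false-call
#' count summarizes, over permutations, the statistics beyond the same two
#' cuts (both tails, so a one-sided excursion is always charged against the
#' permutation distribution's opposite tail as well), and the FDR estimate
#' is false calls over calls, capped at 1 and monotonized to be
#' non-increasing in delta (zero by convention when nothing is called).
#'
#' @param d observed per-feature statistics.
#' @param dbar permutation-expected order statistics (ascending).
#' @param perm_sorted matrix of sorted permuted statistics
#'   (features x permutations).
#' @param deltas increasing grid of thresholds.
#' @param false_stat `"mean"` or `"median"` summary of per-permutation
#'   false-call counts (see [sam_config()]).
#' @param pi0 null-proportion multiplier on the false-call count (1 = off).
#' @return `data.frame` with columns `delta`, `n_called`, `false_called`,
#'   `fdr_estimate`, `cut_lower`, `cut_upper`.
#' @export
delta_fdr_table <- function(d, dbar, perm_sorted, deltas,
                            false_stat = c("mean", "median"), pi0 = 1) {
  false_stat <- match.arg(false_stat)
  summarize <- if (false_stat == "mean") mean else stats::median
  if (!length(deltas)) stop("empty delta grid", call. = FALSE)
  deltas <- sort(deltas)
  ds <- unname(sort(d))
  diff <- ds - dbar
  rows <- lapply(deltas, function(delta) {
    up <- which(dbar >= 0 & diff >= delta)
    cand_up <- if (length(up)) ds[min(up)] else Inf
    lo <- which(dbar <= 0 & diff <= -delta)
    cand_lo <- if (length(lo)) ds[max(lo)] else -Inf
    cut <- min(cand_up, -cand_lo)
    cut_up <- cut
    cut_lo <- -cut
    called <- sum(d >= cut_up | d <= cut_lo)
    false <- summarize(colSums(perm_sorted >= cut_up |
                                 perm_sorted <= cut_lo))
    fdr <- if (called > 0L) min(1, pi0 * false / called) else 0
    data.frame(delta = delta, n_called = called,
               false_called = false, fdr_estimate = fdr,
               cut_lower = cut_lo, cut_upper = cut_up)
  })
  tbl <- do.call(rbind, rows)
  tbl$fdr_estimate <- cummin(tbl$fdr_estimate)
  tbl
}

#' Select the calling threshold for a target FDR
#'
#' @param delta_table output of [delta_fdr_table()].
#' @param target_fdr target false discovery rate.
#' @return list with `delta` (smallest delta whose FDR estimate is at or
#'   below target; the largest delta when none qualifies) and `no_call`
#'   flag.
#' @export
select_delta <- function(delta_table, target_fdr) {
  if (!nrow(delta_table)) stop("empty delta table", call. = FALSE)
  ok <- which(delta_table$fdr_estimate <= target_fdr)
  if (length(ok))
    list(delta = delta_table$delta[min(ok)], no_call = FALSE)
  else
    list(delta = delta_table$delta[nrow(delta_table)], no_call = TRUE)
}

#' Run SAM differential expression between two groups
#'
#' Computes moderated statistics on the normalized log2 matrix, chooses s0,
#' builds the permutation null and the delta/FDR table, selects the delta
#' meeting the target FDR, and attaches raw-scale group means for the
#' downstream intensity/fold-change filters. Group B is the treatment
#' (numerator of reported fold changes), group A the comparator.
#'
#' @param gm a normalized [gene_matrix()].
#' @param ann sample annotation `data.frame`.
#' @param group_a,group_b group selectors (see [back_transform_means()]).
#' @param config a [sam_config()].
#' @return an object of class `sam_result`: per-feature `d`, `s`,
#'   `numerator`, raw-scale `mean_a`/`mean_b`, `s0`, `dbar`, `delta_table`,
#'   `chosen_delta`, `no_call`, `n_permutations`, `exhaustive`, `called`
#'   logical vector at the chosen delta, and the feature table.
#' @export
run_sam <- function(gm, ann, group_a, group_b, config = sam_config()) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(config, "sam_config"))
  if (gm$stage != "normalized")
    stop("run_sam expects a normalized gene_matrix", call. = FALSE)
  ids_a <- intersect(select_samples(ann, group_a), colnames(gm$values))
  ids_b <- intersect(select_samples(ann, group_b), colnames(gm$values))
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  mat <- gm$values[, c(ids_a, ids_b), drop = FALSE]
  idx_a <- seq_along(ids_a)
  idx_b <- length(ids_a) + seq_along(ids_b)

  base <- sam_statistics(mat, idx_a, idx_b, compute_d = FALSE)
  s0 <- choose_s0(base$numerator, base$s, strategy = config$s0_strategy,
                  s0_fixed = config$s0_fixed)
  stat <- sam_statistics(mat, idx_a, idx_b, s0 = s0)

  labels <- rep(c("A", "B"), c(length(ids_a), length(ids_b)))
  null <- permutation_null(mat, labels, s0 = s0,
                           max_permutations = config$max_permutations,
                           seed = config$seed)
  max_dev <- max(abs(sort(stat$d) - null$dbar))
  deltas <- c(seq(0, max_dev, length.out = config$n_deltas - 1L),
              max_dev * 1.01 + 1e-9)
  tbl <- delta_fdr_table(stat$d, null$dbar, null$perm_sorted, deltas,
                         false_stat = config$false_stat, pi0 = config$pi0)
  sel <- select_delta(tbl, config$target_fdr)
  row <- tbl[match(sel$delta, tbl$delta), ]
  called <- stat$d >= row$cut_upper | stat$d <= row$cut_lower

  structure(list(
    features = gm$features,
    d = stat$d, s = stat$s, numerator = stat$numerator, s0 = s0,
    mean_a = rowMeans(2^mat[, idx_a, drop = FALSE]),
    mean_b = rowMeans(2^mat[, idx_b, drop = FALSE]),
    dbar = null$dbar, delta_table = tbl,
    chosen_delta = sel$delta, no_call = sel$no_call,
    fdr_at_selection = row$fdr_estimate,
    cut_lower = row$cut_lower, cut_upper = row$cut_upper,
    called = called & !sel$no_call,
    n_permutations = null$n_permutations, exhaustive = null$exhaustive,
    config = config), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(paste0("sam_result: %d features, s0 = %.4g, %d permutations",
                     " (%s), delta = %.4g, %d called (FDR est. %.3g)\n"),
              length(x$d), x$s0, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$chosen_delta, sum(x$called), x$fdr_at_selection))
  invisible(x)
}

#' Apply the intensity and fold-change filters to SAM calls
#'
#' Keeps features called at the chosen delta whose raw-scale means satisfy
#' `max(mean_a, mean_b) >= intensity_min` and whose fold change
#' `mean_b / mean_a` exceeds `fc_min` in either direction
#' (`fc > fc_min` or `fc < 1/fc_min`). The result is deduplicated to one
#' row per gene symbol, keeping the feature with the largest `|d|`.
#'
#' @param sam a [run_sam()] result.
#' @param config a [sam_config()]; defaults to the one stored in `sam`.
#' @return a `data.frame` (`gene_symbol`, `feature_id`, `fold_change`,
#'   `direction`, `fdr_at_selection`, `mean_a`, `mean_b`, `d`), sorted by
#'   decreasing `|d|`.
#' @export
apply_deg_filters <- function(sam, config = sam$config) {
  stopifnot(inherits(sam, "sam_result"))
  fc <- fold_change(sam$mean_b, sam$mean_a)
  keep <- sam$called &
    pmax(sam$mean_a, sam$mean_b) >= config$intensity_min &
    (fc > config$fc_min | fc < 1 / config$fc_min)
  out <- data.frame(
    gene_symbol = sam$features$gene_symbol[keep],
    feature_id = sam$features$feature_id[keep],
    fold_change = fc[keep],
    direction = ifelse(fc[keep] >= 1, "up", "down"),
    fdr_at_selection = rep(sam$fdr_at_selection, sum(keep)),
    mean_a = sam$mean_a[keep], mean_b = sam$mean_b[keep],
    d = sam$d[keep], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$d)), , drop = FALSE]
  out <- out[!duplicated(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
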