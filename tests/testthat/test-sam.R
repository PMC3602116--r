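test_that("moderated statistic matches the pooled-variance formula", {
  ## zero within-group variance: s = 0, d = diff / s0
  r <- sam_statistic(c(1, 1, 1, 1), c(3, 3, 3, 3), s0 = 1)
  expect_equal(r$s, 0)
  expect_equal(r$d, 2)
  ## hand computation: A=(0,2), B=(4,6) -> s = sqrt(2), d = 4/sqrt(2)
  r2 <- sam_statistic(c(0, 2), c(4, 6), s0 = 0)
  expect_equal(r2$s, sqrt(2))
  expect_equal(r2$d, 4 / sqrt(2), tolerance = 1e-12)
  ## antisymmetry under group swap
  r3 <- sam_statistic(c(4, 6), c(0, 2), s0 = 0)
  expect_equal(r3$d, -r2$d)
  ## degenerate error cases
  expect_error(sam_statistic(c(1), c(2, 3)), "at least 2")
  expect_error(sam_statistic(c(1, 1), c(2, 2), s0 = 0),
               "zero standard error")
  expect_equal(sam_statistic(c(1, 1), c(1, 1), s0 = 0)$d, 0)
})

test_that("s0 selection covers fixed, degenerate and seeded strategies", {
  expect_equal(choose_s0(1:10, rep(1, 10), strategy = "fixed",
                         s0_fixed = 0), 0)
  expect_equal(choose_s0(1:10, rep(1, 10), strategy = "fixed",
                         s0_fixed = 0.7), 0.7)
  ## all s identical: smallest candidate (the common value) returned
  expect_equal(choose_s0(rnorm(20), rep(2, 20)), 2)
  ## on a null dataset the choice lies in the s-percentile grid and is
  ## reproducible
  set.seed(10)
  mat <- matrix(rnorm(2000 * 8, sd = 0.3), 2000, 8)
  st <- sam_statistic
  base <- tissuesam:::sam_statistics(mat, 1:4, 5:8, 0)
  s0a <- choose_s0(base$numerator, base$s)
  s0b <- choose_s0(base$numerator, base$s)
  expect_identical(s0a, s0b)
  expect_true(s0a >= min(base$s) && s0a <= max(base$s))
})

test_that("permutation null enumerates label assignments exhaustively", {
  set.seed(1)
  m4 <- matrix(rnorm(5 * 4), 5, 4)
  null4 <- permutation_null(m4, c("A", "A", "B", "B"), s0 = 0.1)
  expect_equal(null4$n_permutations, 6L)
  expect_true(null4$exhaustive)
  m8 <- matrix(rnorm(10 * 8), 10, 8)
  null8 <- permutation_null(m8, rep(c("A", "B"), each = 4), s0 = 0.1)
  expect_equal(null8$n_permutations, 70L)
  expect_true(null8$exhaustive)
  ## capped: sampled distinct assignments, deterministic under seed
  cap <- permutation_null(m8, rep(c("A", "B"), each = 4), s0 = 0.1,
                          max_permutations = 20L, seed = 5)
  cap2 <- permutation_null(m8, rep(c("A", "B"), each = 4), s0 = 0.1,
                           max_permutations = 20L, seed = 5)
  expect_equal(cap$n_permutations, 20L)
  expect_false(cap$exhaustive)
  expect_identical(cap$perm_sorted, cap2$perm_sorted)
  expect_error(permutation_null(m4, c("A", "B", "B", "B")), "at least 2")
})

test_that("order statistics and delta table match a brute-force oracle", {
  set.seed(21)
  mat <- matrix(rnorm(5 * 4, sd = 1), 5, 4)
  s0 <- 0.2
  oracle <- oracle_sam_null(mat, n_a = 2, s0 = s0)
  null <- permutation_null(mat, c("A", "A", "B", "B"), s0 = s0)
  expect_equal(null$perm_sorted, oracle$perm_sorted, tolerance = 1e-12)
  expect_equal(null$dbar, oracle$dbar, tolerance = 1e-12)
  obs <- tissuesam:::sam_statistics(mat, 1:2, 3:4, s0 = s0)
  expect_equal(obs$d, oracle$d_obs, tolerance = 1e-12)
  deltas <- seq(0, max(abs(sort(obs$d) - null$dbar)) + 0.1,
                length.out = 25)
  tbl <- delta_fdr_table(obs$d, null$dbar, null$perm_sorted, deltas)
  for (i in seq_along(deltas)) {
    o <- oracle_delta_row(oracle$d_obs, oracle$dbar, oracle$perm_sorted,
                          deltas[i])
    expect_equal(tbl$n_called[i], unname(o["called"]))
    expect_equal(tbl$false_called[i], unname(o["false"]))
  }
  ## raw FDR agrees before monotonization wherever monotonization is inert
  o0 <- oracle_delta_row(oracle$d_obs, oracle$dbar, oracle$perm_sorted, 0)
  expect_equal(tbl$fdr_estimate[1], unname(o0["fdr"]))
})

test_that("delta/FDR table boundary and monotonicity behavior", {
  set.seed(31)
  mat <- matrix(rnorm(2000 * 8, sd = 0.3), 2000, 8)
  obs <- tissuesam:::sam_statistics(mat, 1:4, 5:8, 0)
  s0 <- choose_s0(obs$numerator, obs$s)
  obs <- tissuesam:::sam_statistics(mat, 1:4, 5:8, s0)
  null <- permutation_null(mat, rep(c("A", "B"), each = 4), s0 = s0)
  maxdev <- max(abs(sort(obs$d) - null$dbar))
  tbl <- delta_fdr_table(obs$d, null$dbar, null$perm_sorted,
                         c(seq(0, maxdev, length.out = 40),
                           maxdev * 1.01))
  ## pure-null at delta 0: nearly everything called, FDR ~ 1
  expect_gte(tbl$fdr_estimate[1], 0.8)
  ## beyond the largest deviation nothing is called, FDR reported as 0
  last <- nrow(tbl)
  expect_equal(tbl$n_called[last], 0L)
  expect_equal(tbl$fdr_estimate[last], 0)
  ## monotone: calls and FDR non-increasing in delta
  expect_true(all(diff(tbl$n_called) <= 0))
  expect_true(all(diff(tbl$fdr_estimate) <= 1e-12))
  expect_error(delta_fdr_table(obs$d, null$dbar, null$perm_sorted,
                               numeric(0)), "empty delta")
})

test_that("delta selection picks the smallest qualifying threshold", {
  tbl <- data.frame(delta = c(0.1, 0.2), n_called = c(10L, 4L),
                    false_called = c(5, 0.36),
                    fdr_estimate = c(0.5, 0.09))
  sel <- select_delta(tbl, 0.10)
  expect_equal(sel$delta, 0.2)
  expect_false(sel$no_call)
  sel2 <- select_delta(data.frame(delta = c(0.1, 0.2),
                                  fdr_estimate = c(0.5, 0.4)), 0.10)
  expect_equal(sel2$delta, 0.2)
  expect_true(sel2$no_call)
})

test_that("intensity and fold-change filters drop weak calls", {
  mk_sam <- function(mean_a, mean_b, called = TRUE) {
    structure(list(
      features = data.frame(feature_id = "f1", gene_symbol = "g1"),
      d = 3, s = 0.1, numerator = 1, s0 = 0.1,
      mean_a = mean_a, mean_b = mean_b,
      fdr_at_selection = 0.05, called = called,
      config = sam_config()), class = "sam_result")
  }
  ## called but too dim: max(mean) < 150
  expect_equal(nrow(apply_deg_filters(mk_sam(100, 140))), 0L)
  ## called but fold 0.8 inside (1/1.3, 1.3)
  expect_equal(nrow(apply_deg_filters(mk_sam(1000, 800))), 0L)
  ## kept: bright enough and fold 1.6
  kept <- apply_deg_filters(mk_sam(100, 160))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$fold_change, 1.6)
  expect_equal(kept$direction, "up")
  ## decreases reported as raw-scale folds below 1
  down <- apply_deg_filters(mk_sam(1000, 590))
  expect_equal(down$fold_change, 0.59)
  expect_equal(down$direction, "down")
})

test_that("run_sam end-to-end is deterministic and antisymmetric in means", {
  cfg <- two_group_config(seed = 17, n_genes = 250, n_de = 15)
  sim <- generate_array_dataset(cfg)
  gm <- preprocess_probes(sim$probe_matrix)
  scfg <- sam_config(target_fdr = 0.10, seed = 17)
  res <- run_sam(gm, sim$annotation, list(treatment = "control"),
                 list(treatment = "AMPH"), scfg)
  res2 <- run_sam(gm, sim$annotation, list(treatment = "control"),
                  list(treatment = "AMPH"), scfg)
  expect_identical(res$d, res2$d)
  expect_identical(res$delta_table, res2$delta_table)
  swapped <- run_sam(gm, sim$annotation, list(treatment = "AMPH"),
                     list(treatment = "control"), scfg)
  expect_equal(swapped$d, -res$d, tolerance = 1e-12)
  expect_equal(res$n_permutations, 70L)
  expect_true(res$exhaustive)
})

test_that("doubling raw intensities leaves statistics invariant after
           normalization", {
  cfg <- two_group_config(seed = 23, n_genes = 200, n_de = 10)
  sim <- generate_array_dataset(cfg)
  pm <- sim$probe_matrix
  pm2 <- probe_matrix(pm$probes, pm$foreground * 2, pm$background * 2)
  scfg <- sam_config(seed = 23)
  r1 <- run_sam(preprocess_probes(pm), sim$annotation,
                list(treatment = "control"), list(treatment = "AMPH"),
                scfg)
  r2 <- run_sam(preprocess_probes(pm2), sim$annotation,
                list(treatment = "control"), list(treatment = "AMPH"),
                scfg)
  ## doubling shifts every log2 value by +1; the group difference, pooled
  ## SE, and hence d are unchanged up to the floor's edge effects
  expect_equal(r2$d, r1$d, tolerance = 1e-6)
})
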