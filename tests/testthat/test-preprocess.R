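test_that("background subtraction floors net signal at 1 raw unit", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       gene_symbol = c("g1", "g2", "g3"))
  fg <- matrix(c(500, 40, 0), 3, 1, dimnames = list(probes$probe_id, "s1"))
  bg <- matrix(c(50, 60, 0), 3, 1, dimnames = dimnames(fg))
  pm <- subtract_background(probe_matrix(probes, fg, bg))
  expect_equal(unname(pm$signal[, 1]), c(450, 1, 1))
  expect_equal(pm$stage, "background_corrected")
  fg[1] <- -5
  expect_error(subtract_background(probe_matrix(probes, fg, bg)),
               "negative")
})

test_that("probe collapse trims one extreme instance per sample", {
  gm <- collapse_probes(subtract_background(tiny_probe_matrix()))
  v <- gm$values
  ## gene A, 5 probes (10,20,30,40,100): trimmed mean = mean(20,30,40)
  expect_equal(v["A", "s1"], 30)
  expect_equal(v["A", "s2"], 35)
  ## gene B, 3 probes: kept as 3 separate probe-level features
  expect_true(all(paste0("B_p", 1:3) %in% gm$features$feature_id))
  expect_equal(unname(v["B_p1", ]), c(5, 8))
  ## gene C, 4 probes (1,1,1,9): one min and one max discarded -> 1
  expect_equal(v["C", "s1"], 1)
  ## unannotated probe dropped by the gene filter upstream
  gm2 <- collapse_probes(subtract_background(filter_probes(
    tiny_probe_matrix())))
  expect_false("X_p1" %in% gm2$features$feature_id)
  ## n_probes_used bookkeeping
  expect_equal(gm$features$n_probes_used[gm$features$feature_id == "A"], 3L)
  expect_equal(gm$features$n_probes_used[gm$features$feature_id == "B_p1"],
               1L)
})

test_that("probe collapse is invariant to probe order and equals the plain
           mean when probes agree", {
  pm <- subtract_background(tiny_probe_matrix())
  perm <- sample(nrow(pm$probes))
  pm2 <- probe_matrix(pm$probes[perm, ], pm$foreground[perm, ],
                      pm$background[perm, ], signal = pm$signal[perm, ],
                      stage = pm$stage)
  a <- collapse_probes(pm)
  b <- collapse_probes(pm2)
  common <- intersect(a$features$feature_id, b$features$feature_id)
  expect_setequal(a$features$feature_id, b$features$feature_id)
  expect_equal(a$values[common, ], b$values[common, ])
  ## all probes equal -> trimmed mean equals the value itself
  probes <- data.frame(probe_id = paste0("e_p", 1:5), gene_symbol = "e")
  fg <- matrix(80, 5, 2, dimnames = list(probes$probe_id, c("s1", "s2")))
  bg <- matrix(0, 5, 2, dimnames = dimnames(fg))
  ge <- collapse_probes(subtract_background(probe_matrix(probes, fg, bg)))
  expect_equal(unname(ge$values["e", ]), c(80, 80))
})

test_that("log2 transform applies only to positive background-corrected
           values", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       gene_symbol = c("a", "b", "c"))
  fg <- matrix(c(8, 1, 150) + 10, 3, 1,
               dimnames = list(probes$probe_id, "s1"))
  bg <- matrix(10, 3, 1, dimnames = dimnames(fg))
  gm <- log2_transform(collapse_probes(subtract_background(
    probe_matrix(probes, fg, bg))))
  expect_equal(unname(gm$values[, 1]), c(3, 0, log2(150)))
  expect_equal(unname(gm$values[3, 1]), 7.2288, tolerance = 1e-4)
  expect_equal(gm$stage, "log2")
})

test_that("quantile normalization matches the rank-mean hand example and is
           idempotent", {
  probes <- data.frame(probe_id = paste0("p", 1:3),
                       gene_symbol = paste0("g", 1:3))
  mk <- function(m) gene_matrix(data.frame(
    feature_id = probes$probe_id, gene_symbol = probes$gene_symbol,
    n_probes_used = 1L), m, stage = "log2")
  m <- cbind(s1 = c(2, 4, 6), s2 = c(3, 5, 7))
  rownames(m) <- probes$probe_id
  qn <- quantile_normalize(mk(m))
  expect_equal(unname(qn$values[, "s1"]), c(2.5, 4.5, 6.5))
  expect_equal(unname(qn$values[, "s2"]), c(2.5, 4.5, 6.5))
  expect_equal(qn$stage, "normalized")
  ## idempotence and identical sorted columns on random input
  set.seed(42)
  m2 <- matrix(rnorm(300), 100, 3,
               dimnames = list(paste0("r", 1:100), paste0("s", 1:3)))
  g2 <- gene_matrix(data.frame(feature_id = rownames(m2),
                               gene_symbol = rownames(m2),
                               n_probes_used = 1L), m2, stage = "log2")
  q1 <- quantile_normalize(g2)
  sorted <- apply(q1$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  q2 <- quantile_normalize(gene_matrix(q1$features, q1$values,
                                       stage = "log2"))
  expect_equal(q2$values, q1$values, tolerance = 1e-12)
  ## rank order within sample preserved
  expect_equal(apply(q1$values, 2, rank), apply(m2, 2, rank))
  ## fixed point: identical samples unchanged
  m3 <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  rownames(m3) <- probes$probe_id
  expect_equal(quantile_normalize(mk(m3))$values, m3)
  ## single sample: warning, unchanged
  expect_warning(q4 <- quantile_normalize(mk(m3[, 1, drop = FALSE])),
                 "single sample")
  expect_equal(q4$values, m3[, 1, drop = FALSE])
})

test_that("back-transformed group means and fold changes are raw-scale", {
  feats <- data.frame(feature_id = c("f1", "f2"),
                      gene_symbol = c("f1", "f2"), n_probes_used = 1L)
  vals <- rbind(f1 = c(3, 3, 1, 3), f2 = c(1, 3, 2, 2))
  colnames(vals) <- paste0("s", 1:4)
  gm <- gene_matrix(feats, vals, stage = "normalized")
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    tissue = "MAV",
                    treatment = c("control", "control", "AMPH", "AMPH"),
                    timepoint = "3hr", slide_id = "sl1")
  m_ctrl <- back_transform_means(gm, ann, list(treatment = "control"))
  expect_equal(unname(m_ctrl), c(8, (2 + 8) / 2))
  expect_error(back_transform_means(gm, ann, list(treatment = "EIH")),
               "no samples")
  expect_equal(fold_change(300, 100), 3)
  expect_equal(fold_change(100, 100), 1)
  expect_equal(round(fold_change(2.23, 0.11), 2), 20.27)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("a group mean constructed to hit a printed table value is
           reproduced after back-transform", {
  ## four samples whose 2^value average to 2433.0 exactly
  target <- 2433.0
  raw <- c(2000, 2600, 2500, 2632)
  stopifnot(mean(raw) == target)
  feats <- data.frame(feature_id = "Aqp1", gene_symbol = "Aqp1",
                      n_probes_used = 3L)
  vals <- matrix(log2(raw), 1, dimnames = list("Aqp1", paste0("s", 1:4)))
  gm <- gene_matrix(feats, vals, stage = "normalized")
  ann <- data.frame(sample_id = paste0("s", 1:4), tissue = "MAV",
                    treatment = "control", timepoint = "3hr",
                    slide_id = "sl1")
  expect_equal(unname(back_transform_means(gm, ann,
                                           list(treatment = "control"))),
               target)
})

test_that("zero-noise planted fold changes are recovered exactly", {
  ## no noise and no array bias: normalization has nothing to remove, so
  ## the collapse/log2/back-transform chain must reproduce the planted
  ## 2^effect fold exactly
  cfg <- two_group_config(seed = 7, n_genes = 150, n_de = 10,
                          de_log2_effect = 2, array_noise_sd = 0,
                          array_scale_sd = 0)
  sim <- generate_array_dataset(cfg)
  gm <- preprocess_probes(sim$probe_matrix, normalize = FALSE)
  ann <- sim$annotation
  ma <- back_transform_means(gm, ann, list(treatment = "control"))
  mb <- back_transform_means(gm, ann, list(treatment = "AMPH"))
  tr <- sim$truth$de_genes
  for (i in seq_len(nrow(tr))) {
    f <- gm$features$feature_id[gm$features$gene_symbol == tr$gene[i]][1]
    expect_equal(unname(fold_change(mb[f], ma[f])), 2^(2 * tr$sign[i]),
                 tolerance = 1e-9)
  }
})
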