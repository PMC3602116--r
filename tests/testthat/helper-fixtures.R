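## Small in-code fixtures shared across test files.

## two-group, single-tissue design used by most SAM tests
two_group_config <- function(seed = 1, n_genes = 200, n_de = 0, ...) {
  sim_config(n_genes = n_genes, n_de_genes = n_de, tissues = "MAV",
             groups = list(c("control", "3hr"), c("AMPH", "3hr")),
             n_samples_per_cell = 4, seed = seed, ...)
}

## a tiny hand-built probe matrix: gene A (5 probes), gene B (3 probes),
## gene C (4 probes with ties), one probe without a symbol
tiny_probe_matrix <- function() {
  probes <- data.frame(
    probe_id = c(paste0("A_p", 1:5), paste0("B_p", 1:3),
                 paste0("C_p", 1:4), "X_p1"),
    gene_symbol = c(rep("A", 5), rep("B", 3), rep("C", 4), ""),
    stringsAsFactors = FALSE)
  fg <- cbind(
    s1 = c(10, 20, 30, 40, 100, 5, 6, 7, 1, 1, 1, 9, 50) + 50,
    s2 = c(15, 25, 35, 45, 105, 8, 9, 10, 2, 2, 2, 10, 60) + 50)
  bg <- matrix(50, nrow(fg), ncol(fg), dimnames = dimnames(fg))
  rownames(fg) <- rownames(bg) <- probes$probe_id
  probe_matrix(probes, fg, bg)
}

## control-condition means from the published-style selected-gene table
## (choroid plexus vs parietal cortex / striatum, MAV as blood stand-in off)
selected_gene_means <- function() {
  rbind(Aqp1  = c(choroid_plexus = 8576.6, parietal_cortex = 33.9,
                  striatum = 31.0),
        Mmp14 = c(6744.9, 195.9, 277.3),
        Cldn5 = c(274.4, 2222.5, 2505.1),
        Cldn9 = c(1335.8, 147.3, 364.0))
}

## brute-force oracle: exhaustive SAM null + delta table via scalar loops,
## written independently of the package's vectorized implementation
oracle_sam_null <- function(mat, n_a, s0) {
  n <- ncol(mat)
  combos <- utils::combn(n, n_a, simplify = FALSE)
  d_of <- function(idx_a) {
    idx_b <- setdiff(seq_len(n), idx_a)
    sapply(seq_len(nrow(mat)), function(i) {
      xa <- mat[i, idx_a]; xb <- mat[i, idx_b]
      ss <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
      s <- sqrt((1 / length(xa) + 1 / length(xb)) * ss /
                  (length(xa) + length(xb) - 2))
      (mean(xb) - mean(xa)) / (s + s0)
    })
  }
  perm <- sapply(combos, function(ix) sort(d_of(ix)))
  list(perm_sorted = perm, dbar = rowMeans(perm),
       d_obs = d_of(seq_len(n_a)))
}

oracle_delta_row <- function(d_obs, dbar, perm, delta, summarize = mean) {
  ds <- sort(d_obs)
  cand_up <- Inf
  for (i in seq_along(ds))
    if (dbar[i] >= 0 && ds[i] - dbar[i] >= delta) { cand_up <- ds[i]; break }
  cand_lo <- -Inf
  for (i in rev(seq_along(ds)))
    if (dbar[i] <= 0 && ds[i] - dbar[i] <= -delta) { cand_lo <- ds[i]; break }
  cut <- min(cand_up, -cand_lo)
  cut_up <- cut; cut_lo <- -cut
  called <- sum(d_obs >= cut_up | d_obs <= cut_lo)
  false <- summarize(apply(perm, 2, function(col)
    sum(col >= cut_up | col <= cut_lo)))
  fdr <- if (called > 0) min(1, false / called) else 0
  c(called = called, false = false, fdr = fdr)
}

## minimal GEO series-matrix text fixture (3 genes x 2 samples), with a
## quoted sample title containing a tab
series_matrix_fixture <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "!Series_title\t\"Synthetic series for parser tests\"",
    "!Series_geo_accession\t\"GSE00000\"",
    "!Sample_title\t\"brain\ttissue 1\"\t\"brain tissue 2\"",
    "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "\"probeA\"\t1.5\t2.5",
    "\"probeB\"\t3\t4",
    "\"probeC\"\t5.25\t6.75",
    "!series_matrix_table_end"), path)
  path
}
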