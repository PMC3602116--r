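---
title: "Models and methods behind tissuesam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tissuesam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuesam)
```

tissuesam analyzes one-color oligonucleotide array expression in brain
tissues with very different cellular composition — vascular-rich meninges
and associated vasculature (MAV) and choroid plexus versus neuronal-rich
striatum and parietal cortex — under control, hyperthermia (EIH) and
amphetamine (AMPH) conditions, plus RT-PCR follow-up. This vignette
documents the models, the tunable parameters, the numerical choices, and
the limits of what the test suite demonstrates.

## The preprocessing model

Raw probe intensities are modeled and processed on the log2 scale, where
array data are approximately symmetric and variance is more stable:

1. **Gene filter.** Probes without a non-empty gene symbol are dropped.
   No live validation against a symbol database is attempted.
2. **Background correction.** `signal = max(foreground − background, 1)`.
   The floor of 1 raw unit keeps spots whose local background exceeds the
   foreground at a defined "low" value instead of producing negative or
   −∞ values downstream; its exact magnitude is immaterial because such
   spots sit at the bottom of every ranking that follows.
3. **Probe collapse.** Genes with < 4 probes keep each probe as a separate
   feature; genes with ≥ 4 probes become one feature per gene, the
   per-sample mean after discarding exactly one minimum and one maximum
   probe value *in that sample*. Trimming per sample (rather than trimming
   probes by their cross-sample average) is the more robust reading of a
   trimmed-average rule and is what the synthetic probe offsets exercise;
   with ties at an extreme, a single instance is discarded, so
   probes (1, 1, 1, 9) collapse to mean(1, 1) = 1.
4. **log2 transform**, then **quantile normalization** — classic rank-mean
   substitution (delegated to `limma::normalizeQuantiles` with tie
   averaging, so ties within a sample receive the mean of the tied ranks'
   reference values). Afterwards every sample has an identical sorted
   value vector; the transform is idempotent and preserves within-sample
   rank order.

Reported intensities and fold changes go back through the inverse
transform: per feature, the *arithmetic* mean of `2^value` over a group's
samples, and ratios of those means. The geometric alternative
(`2^mean(value)`) is available via `back_transform_means(geometric =
TRUE)` but is not the default, because the reporting convention here is
back-transform first, then average.

### When quantile normalization is the wrong tool

Quantile normalization assumes all arrays share an intensity
distribution. Arrays from tissues with strong tissue-specific expression
violate that assumption, and the violation concentrates in the extreme
tail: a gene 16-fold enriched in one tissue sits at ranks that other
tissues' arrays fill with ordinary genes, so cross-tissue normalization
pulls its value toward the pooled tail and compresses the very folds the
enrichment analysis measures. The effect is acute for the synthetic
generator, whose baseline is normal on the log2 scale (thin-tailed):
planted 16-fold enrichment can compress below the 15-fold calling
threshold even with only a few percent of genes planted. Real array data
have heavier tails filled by thousands of graded tissue-specific genes and
suffer much less. Consequently:

* the differential-expression path (contrasts within one tissue) always
  quantile-normalizes, which is what the bias-removal is for;
* the zero-noise recovery checks of the enrichment caller run on the
  collapse/log2 chain without normalization
  (`preprocess_probes(normalize = FALSE)`) — with no array bias and no
  noise there is nothing for normalization to remove, and the check
  isolates the caller's own correctness;
* `run_pipeline()` keeps global normalization as the default for real
  data, matching standard practice for this array generation.

## The differential-expression model

For features `i` and a two-group contrast with `n₁, n₂ ≥ 2` arrays, the
moderated statistic is

```
d_i = (mean2_i − mean1_i) / (s_i + s0)
s_i = sqrt((1/n1 + 1/n2) * (SS1_i + SS2_i) / (n1 + n2 − 2))
```

`s0` stabilizes low-variance features. By default it is chosen by
coefficient-of-variation minimization: candidates are the 0, 5, …, 100th
percentiles of the `s` distribution; for each candidate, the spread
(median absolute deviation) of the moderated statistics is measured within
`s`-quantile windows, and the candidate minimizing the CV of those spreads
wins, ties toward smaller `s0`. When some features have exactly zero
pooled standard error (possible after tie-averaged normalization of
floored spots), a zero candidate would leave their statistic undefined, so
zero candidates are dropped. A fixed `s0` is available
(`s0_strategy = "fixed"`).

**Permutation null.** All `choose(n1 + n2, n1)` label assignments are
enumerated when that count is at most `max_permutations` (70 for 4 vs 4,
well within the default cap of 10,000); beyond the cap, distinct
assignments are sampled with the seeded generator. Every permutation
recomputes both the mean difference and the standard error; `s0` is held
fixed. Sorting each permutation's statistics and averaging by rank gives
the expected order statistics `dbar`.

**Calling and FDR.** For a threshold delta, scanning from the origin
outward, the first sorted rank where `d − dbar ≥ delta` (above) or
`≤ −delta` (below) yields cut candidates; the final cut values are
symmetric, `±cut` with `cut` the smaller candidate magnitude. Features
beyond the cuts are called. The estimated number of false calls is the
**mean** over permutations of statistics beyond the same two cuts, and
FDR = false/called, capped at 1 (0 when nothing is called) and monotonized
(non-increasing in delta). Two deliberate choices here:

* *Mean, not median, false counts.* The per-permutation false-count
  distribution is strongly right-skewed; its median collapses to zero
  whenever more than half the permutations put nothing beyond the cuts,
  which brands 1–2-gene spurious call sets "FDR = 0" on fully null data.
  The mean — the convention of the original SAM formulation — keeps those
  estimates honest. The median remains available
  (`sam_config(false_stat = "median")`).
* *Symmetric cut values.* Charging both permutation tails against a
  one-sided excursion makes a single extreme feature pay for the null
  distribution's opposite tail too. On fully null simulated data (2,000
  genes, 4 vs 4, nominal FDR 0.10) the combination yields zero calls after
  filters in ~93–95% of datasets, with a mean false-discovery proportion
  well under 0.1, while sensitivity on planted 4-fold effects is
  unaffected.

The selected delta is the smallest whose FDR estimate meets the target
(0.10 for the 3 hr design, 0.20 for 1 day, per the study's settings); if
none qualifies the result is flagged no-call. Called features then pass
the reporting filters: raw-scale mean ≥ 150 in at least one group, and
fold change > 1.3 or < 1/1.3. Gene-level lists deduplicate probe-level
features by largest |d|. No π0 correction is applied by default
(`sam_config(pi0 =)` exposes one as a plain multiplier).

## The enrichment model

Given raw-scale control means per tissue, a gene's `min_fold` is its
target-tissue mean divided by the *larger* of the two reference-tissue
means — i.e. the fold it clears against both references. Enrichment
requires `min_fold ≥ fold_threshold` (15 default, 10 variant) and
survival of the blood rule: a gene whose blood mean is ≥ 5× its
target-tissue mean is treated as probable residual-blood signal and never
called, since these tissues cannot be perfused free of blood. Enriched
genes are binned ">50", "30–50", "15–30"; bin edges assign a boundary
fold (exactly 50 or 30) to the lower bin, a documented convention since
published tables are ambiguous at one boundary case.

Expected-versus-observed counting treats the array-wide proportion `p` of
enriched genes as a null rate for a DEG list of size `m`:
`expected = round(p · m)`, `observed = |DEG ∩ enriched|`. With the
published inputs — 272 enriched genes of ~11,000 (p ≈ 2.5%) and DEG lists
of 265, 1,129 and 70 — the expected counts are 7, 28 and 2. No
significance test is attached by default (the comparison is reported as
raw counts); `expected_observed_counts(binomial_p = TRUE)` adds a binomial
tail probability. Cross-tissue agreement is summarized by directional
overlap fractions (`|A ∩ B| / |A|`) and by the Pearson correlation of
per-gene control means, computed on the log2 scale by default since raw
intensities span orders of magnitude (raw-scale via `log2 = FALSE`).

## The qPCR model

Technical duplicates are averaged on the Ct scale per (sample, gene) —
standard practice, since Ct is the measurement scale. A sample's gene
measurement with (averaged) Ct above 35 cycles is below the limit of
quantification and reported "N.E."; Ct = 35.0 still counts as expressed.
Expressed genes get `2^-(Ct_gene − Ct_ref) × 100`, percent of the
reference gene (Gapdh) in the same sample, which makes the reference's own
relative quantity exactly 100. Group summaries report mean ± SD over
expressed samples and a fold against the design's comparator: control for
the 3 hr three-arm design, EIH for the 1 day two-arm design (which has no
control arm); both comparators are explicit configuration. Significance
uses rank statistics at the 5% level: Kruskal–Wallis (tie-corrected)
followed by Dunn's pairwise z tests with Holm adjustment for 3 hr —
Dunn/Holm is a documented assumption, as the original adjustment method is
not recoverable; Bonferroni is available — and the two-sided Mann–Whitney
U (exact for small untied samples) for 1 day.

## The synthetic-data generator

The generator emulates the study design: four tissues × {control, EIH,
AMPH} × {3 hr, 1 day} (control at 3 hr only, as dosed), n = 4 arrays per
cell by default, ~2.4 probes per gene with the bulk of genes at 1–3 probes
and a tail to 7. The signal model on the log2 scale:

```
value[probe, array] = gene_baseline + probe_offset + tissue_effect
                      + treatment_effect + array_bias + noise
foreground = background_spot + 2^value ;  background reported alongside
```

| parameter | default | meaning |
|---|---|---|
| `baseline_log2_mean`, `baseline_log2_sd` | 8, 1.5 | per-gene baseline (raw scale ≈ 256, spanning ~30–2,000) |
| `probe_offset_sd` | 0.5 | fixed per-probe affinity offset; makes the trimmed collapse consequential |
| `array_noise_sd` | 0.25 | per-measurement noise, a typical within-group CV for replicate arrays |
| `array_scale_sd` | 0.1 | per-array multiplicative bias (log2-additive), what normalization removes |
| `background_mean`, `background_sd` | 50, 10 | spot background, raw units |
| `de_log2_effect` | 2 | planted 4-fold treatment effect, random sign per gene |
| `enrichment_log2_effect` | 4 | planted 16-fold tissue enrichment — just above the 15-fold threshold so recovery is a meaningful check |
| `blood_log2_effect` | 3 | planted 8-fold blood elevation — comfortably above the 5-fold exclusion rule |

Three structural choices matter for interpretation. Spot background is
drawn once per probe and held constant across arrays — a per-spot
property — so background subtraction is exact by construction and the
zero-noise configuration (`array_noise_sd = 0, array_scale_sd = 0`)
produces literally identical arrays within a group, the anchor for the
exact-recovery tests. Blood arrays are generated only under the control
condition, which is the only condition the exclusion rule uses. Choroid
plexus pooling of 2–3 animals per aliquot is modeled only as a
`sqrt(pooling_factor)` shrink of measurement noise in that tissue; no
between-animal variance component is simulated.

Ct tables are generated per sample as reference Ct (default 20) minus
log2 of the gene's configured relative abundance, plus per-replicate noise
(SD 0.15 cycles); nonexpressed genes draw Ct uniformly in (35.5, 40).

**What passing tests do and do not show.** The generator draws normal
log2 baselines and effects — it has no heavy tails, no probe-sequence or
GC effects, no spatial artifacts, no correlated gene modules, no
between-animal biological variance beyond the array noise. Recovery of
planted effects therefore demonstrates the pipeline's statistical
machinery, not performance on real arrays; in particular the thin tail
makes cross-tissue quantile normalization *harsher* on planted enrichment
than real data would be (see above), and the absence of gene-gene
correlation makes permutation FDR estimates better behaved than on real
co-regulated transcriptomes.

## Problem sizes and numerics

The test suite and the acceptance script use 2,000-gene datasets with
4 vs 4 arrays (70 exhaustive permutations) and 20 replicate datasets for
the stochastic properties — large enough that empirical sensitivities and
false-discovery proportions are stable to a few percent, and the whole
suite runs in well under a minute. The delta grid spans
[0, max|d − dbar|] in 101 points, with one point beyond the maximum so the
zero-call boundary is always represented. Seeds propagate from a single
integer per run; identical configuration and seed give byte-identical
outputs, including TSV files and the pipeline manifest hash (which covers
the analysis configuration, not the output location).

## Known limitations

* The delta-selection rule ("smallest delta whose estimated FDR meets the
  target") acts on a noisy estimate; on fully null data a single extreme
  feature still slips through in roughly 5–7% of datasets. This is
  intrinsic to threshold selection on permutation FDR estimates at n = 4
  per group.
* Only two-class unpaired contrasts are supported — no multi-class,
  paired, or time-course statistics.
* The GEO series-matrix reader is a convenience loader for the standard
  dialect; it does not implement the full SOFT specification.
* Enrichment functional categories are a passthrough annotation column,
  not computed; no pathway analysis is included.
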