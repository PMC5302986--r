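---
title: "Methods: inverse-correlation inference of functional miRNA targets"
author: "mirtam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse-correlation inference of functional miRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtam)
```

## The problem

Tamoxifen-resistant breast cancer cell lines (three independent resistant
clones derived from a parental MCF-7 subline) show widespread changes in
both miRNA and mRNA expression. Computational miRNA target prediction is
notoriously permissive, so the question this package addresses is: *which
predicted miRNA-target pairs are actually functional in this system?* The
working assumption is the canonical one: a regulating miRNA represses its
target, so the miRNA's abundance and the target's mRNA level should move
in opposite directions across conditions.

The twist is that miRNA abundance here is measured by qPCR crossing
points (Cp), which are themselves *inversely* proportional to abundance
(one fewer cycle to threshold for every doubling of template). A
repressed target therefore tracks its regulator's Cp *positively*, and
the package's correlation statistic is the **negated** Pearson
correlation between Cp condition means and expression condition means: a
strongly negative value (at or below -0.8) is evidence of inverse
abundance-expression coupling. A pair is called a *predicted functional
target* when this negated correlation is <= -0.8 **and** at least 2 of
the 6 prediction tools consumed as input (miRanda, miRDB, miRWalk,
PicTar, RNA22, TargetScan) support it. Both comparisons are inclusive.

The correlation is computed over exactly the four condition means (one
parental, three resistant), i.e. n = 4 points per pair. We implement the
joint four-condition matrix (all cell lines at once) rather than one
matrix per resistant line; the per-line alternative is available by
subsetting the condition means, but the joint reading is the default. At
n = 4 a threshold of r <= -0.8 is a *screening heuristic*, not a
calibrated test — under the null the correlation of 4 centered points is
uniform on [-1, 1], so a random predicted pair passes the r-gate with
probability 0.1. That false-positive pressure is exactly what the
>= 2-predictor support gate and the fold-change candidate filter exist to
suppress. The module refuses to correlate fewer than 3 shared conditions.

## Pipeline stages

1. **Melting-curve QC** (`count_melt_peaks`, `melt_qc`). Fluorescence is
   smoothed by a 3-point moving average, differentiated against
   temperature, and local maxima of -dF/dT are counted; peaks below 20%
   of the tallest peak are treated as ripple. Assays with more than one
   peak (more than one amplified product) are flagged for exclusion.
   These two parameters are package choices; the assay platform does not
   prescribe them.
2. **Quantile-spline normalization** (`fit_qspline`,
   `apply_normalization`, `sem_reduction`). Per-sample Cp quantiles at
   101 anchors are mapped to a target distribution (the across-sample
   mean of per-sample quantiles — symmetric in the samples and standard
   practice for signal-dependent qPCR normalization); anchor offsets are
   smoothed by a cubic smoothing spline and the final map is made
   non-decreasing by isotonic adjustment, so within-sample ranks are
   never altered. Details in "Numerical choices" below.
3. **Differential expression** (`de_test`, `de_counts`,
   `consistent_signature`, `select_candidates`). A moderated two-sample
   t-statistic per feature: the pooled variance is shrunk toward the
   across-feature mean variance with prior weight `d0 = 2`
   pseudo-replicates. On the Cp scale the mean difference is negated so
   positive log2 fold change always means more abundant miRNA. The
   cross-cell-line signature keeps features significant (BH-adjusted
   p < 0.05) with the same sign in all three resistant-vs-parental
   contrasts. Candidate miRNAs for integration are selected by
   |log2FC| >= 0.7 in at least one contrast, with no p-value condition.
4. **Small-RNA quantification** (`trim_reads`, `dedupe_reads`,
   `sequence_groups`, `match_reads`, `size_factors`). Reads are adapter-
   and quality-trimmed (running-sum algorithm at Q20), dropped below
   15 nt, collapsed to unique sequences, and matched *exactly* (substring
   in either direction, no mismatches or gaps) against the mature
   reference. Reads hitting more than one distinct reference sequence are
   discarded as multi-mapped — but identical mature sequences (paralog
   families) are first collapsed into a single sequence group, because a
   literal per-identifier discard would zero out every such family.
   Counts are scaled by median-of-ratios size factors.
5. **Target integration** (`condition_means`, `correlate`,
   `infer_functional_targets`, `regulation_coverage`) as described above.
   `regulation_coverage` reports the fraction of differentially expressed
   genes that are functional targets of at least one differentially
   expressed miRNA, together with a 2x2 table (DE vs not-DE x targeted vs
   not-targeted over a stated gene universe) for `odds_ratio`. The 2x2
   construction is a declared package definition.
6. **Enrichment statistics** (`wilcoxon_enrichment`, `enrichment_suite`,
   `odds_ratio`, `ora_hypergeometric`). Per miRNA, a two-sided rank-sum
   test compares fold changes of its functional targets against all
   non-targeted genes — deliberately including predicted-but-not-
   functional targets in the background. The signed log10 p is -log10(p)
   with a negative sign when targets rank *lower* (more downregulated)
   than the background, so functional targets of an upregulated miRNA
   produce a negative value. `ora_hypergeometric` is generic plumbing for
   user-supplied gene-set collections; no pathway database ships with the
   package.
7. **Outcome classification** (`fit_logistic`, `roc_auc`,
   `cross_cohort_matrix`). Logistic recurrence classifiers over marker
   miRNA combinations, fitted per cohort and evaluated on every cohort;
   fit-equals-test entries are flagged as training (resubstitution)
   performance. Standardization parameters are learned on the fit cohort
   only and reapplied to test cohorts — with independently processed
   cohorts this is the defensible default, and reports carry the flag.

## What the synthetic-data generator emulates

`sim_config()` fixes the study conditions; `simulate_truth()` plants a
regulatory network and `simulate_expression()` realizes it:

* **Design**: 30 miRNAs, 200 genes, 150 repression edges, 4 conditions
  (1 parental + 3 resistant), 3 biological replicates, matching the cell
  line panel's shape.
* **Inverse coupling**: gene log2 expression = baseline - sum over
  incoming edges of (strength x centered condition-level miRNA log2
  abundance) + N(0, 0.2). Cp = 35 - log2 abundance + per-sample bias +
  N(0, 0.2), so abundance and Cp are exactly anti-monotone.
* **Condition shifts**: every miRNA receives per-condition log2 shifts
  with magnitude U(0.8, 3) and a sign drawn per (miRNA, condition). The
  per-condition signs model independently derived resistant clones,
  which share only part of their alterations — and they are also what
  makes each planted edge *identifiable*: with one global sign per
  miRNA, all same-sign miRNAs would load on the single
  parental-vs-resistant axis, their 4-point profiles would be mutually
  collinear, and pairwise correlation could not attribute a regulated
  gene to its true regulator even at zero noise.
* **Single regulator per gene (default)**: while edges <= genes, each
  edge gets a distinct target. Pairwise correlation over 4 condition
  means cannot deconvolve combinatorial regulation (two equal regulators
  attenuate each pairwise correlation to about -0.71, below the -0.8
  gate), so a generator meant to provide a *recoverable* planted truth
  assigns one regulator per gene. Real data is combinatorial; passing
  the recovery suite therefore shows the inference machinery is correct,
  not that real networks are fully recoverable at n = 4.
* **Plate bias**: a smooth per-sample quadratic of the Cp signal, scaled
  by the amplitude parameter (default 1.5 Cp), with coefficients
  centered across samples and a global bound |b'| <= 0.4. Centering
  reflects identifiability — normalizing to the across-sample mean
  target can only recover offsets relative to the sample average — and
  the derivative bound reflects that real plate distortions warp the Cp
  scale gently; where 1 + b' approaches 0 the distortion compresses the
  scale so strongly that measurement noise swamps it and no method could
  invert it. `planted_offset()` exposes the ground-truth correction
  -b(g^-1(y)) by numerically inverting the distortion.
* **Predictions**: every true edge is backed by >= 2 distinct predictors;
  decoy (non-edge) pairs enter at rate 0.1 with support drawn from a
  truncated geometric (P(support = 1) = 0.7), so most decoys fall below
  the support gate but some pass it and must be removed by the
  correlation filter.
* **Reads**: multinomial draws proportional to linear abundance; each
  read is the mature sequence plus an optional 3' adapter, truncated to
  36 nt, with qualities decaying over the adapter tail. No sequencing
  errors, isomiRs or length heterogeneity are simulated.
* **Cohorts**: three cohorts of 52/60/40 patients; recurrence labels are
  drawn from a logistic model on standardized marker expression with
  cohort intercepts (0, 0, -0.1), giving prevalences near 0.5/0.5/0.475.
  Default coefficients (1.5, -1.5, 0, 0) plant a two-marker signal with
  two null markers, so multi-marker combinations can beat single
  markers on independent test cohorts.

Features of real data deliberately *not* emulated: combinatorial 3'UTR
regulation (see above), transcription-factor feedback on miRNAs,
sequence-level target-site thermodynamics (predictions are tabular),
isomiR and degradation products, batch structure between cohorts, and
censoring/time-to-event in the clinical outcome.

## Numerical choices

* **Quantile anchors** sit at plotting positions (i - 0.5)/101 rather
  than spanning 0..1 inclusively: the exact sample minimum and maximum
  are noise-dominated order statistics.
* **Spline smoothing** uses generalized cross-validation with the
  effective degrees of freedom capped at 8. Offsets at neighbouring
  anchors share order statistics, so their errors are strongly
  correlated; GCV assumes independent errors and, left alone, chooses
  50-60 df and chases quantile noise, producing non-monotone boundary
  wiggle. The offset being estimated is smooth and low-order by nature.
* **Isotonic correction** (pool-adjacent-violators on the final map
  x + offset(x)) guarantees rank preservation; it leaves an already
  monotone map untouched. Offsets are tabulated over each sample's full
  observed range (the spline extrapolates past the outermost anchors);
  *new* values outside that range receive the boundary offset, and
  renormalizing normalized data reproduces it to within 0.05 Cp.
* **Moderated-t p-values** integrate the exact null of the statistic
  T = Z / sqrt(w0 + w1 V), V ~ chi-square(df)/df, numerically (401
  midpoint nodes over V). Referring T to a t distribution with d0 + df
  degrees of freedom — as if the shrinkage target were an independent
  chi-square prior — is measurably conservative here, because the
  across-feature mean variance has negligible spread.
* **Rank-sum test**: exact null distribution (tail doubling, capped at
  1) when both sides have <= 10 observations and the data are tie-free;
  otherwise the normal approximation with mid-rank tie correction and
  continuity correction.
* **Fisher p** for 2x2 tables doubles the smaller hypergeometric tail
  (capped at 1). This deliberately differs from the point-probability
  summation convention of `stats::fisher.test`. The odds ratio applies
  the Haldane 0.5 correction only when a cell is zero.
* **Logistic regression**: Newton-Raphson with step halving, a ridge
  penalty of 1e-6 on the slopes so separable data stay finite,
  convergence at gradient norm < 1e-8 or 500 iterations.
* **Counts** are tested on log2(normalized + 0.5); all-zero features are
  reported untested rather than given p-values.
* **Missing Cp** (undetected assays) propagate as NA; a replicate mean
  over fewer than 2 detected values is treated as missing, and features
  missing in any condition are excluded from correlation (tallied, not
  silently lost).

## Problem sizes used by the test suite

The suite validates planted-truth recovery on the default design (30
miRNAs x 200 genes x 150 edges, 12 samples; precision and recall both
>= 0.8 against the planted edges), normalization recovery on a
750-assay panel (panel-scale, amplitude 1.5, RMS error < 0.1 Cp at the
anchors), type-I calibration on 1,000 null features and 500 null
rank-sum replicates (3 sigma around 0.05), oracle equivalence on ~1,000
random instances per statistic, and classifier coefficient recovery at
n = 2,000. These sizes are the package's validation design; all run from
fixed seeds.

## Known limitations

* r <= -0.8 over 4 condition means is a screen; it has no sampling
  calibration and inherits a 10% null pass rate per predicted pair.
* The count-scale test is a moderated t on log-transformed normalized
  counts, not a negative-binomial model; no dispersion trend or
  empirical-Bayes prior-df estimation is performed.
* Exact substring matching cannot place reads with sequencing errors;
  they fall into the unmatched tally.
* The consistency signature treats contrasts as exchangeable and
  requires strict sign agreement; a miRNA strongly altered in two lines
  and flat in the third is excluded by design.
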