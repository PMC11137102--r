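---
title: "Methods: cfDNA CIN stratification, nucleosome and methylation scoring"
author: "cfcin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA CIN stratification, nucleosome and methylation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plasma cell-free DNA (cfDNA) of cancer patients is a mixture: a fraction
`tf` (the *tumor fraction*) derives from tumor cells, the rest from normal
hematopoietic turnover. Metastatic colorectal cancers stratify into
chromosomal-instability (CIN) clusters — a near-diploid cluster 1 with
poor outcome under anti-angiogenic therapy, and two aneuploid clusters 2
and 3 that respond better. `cfcin` implements the full analysis chain
needed to make that stratification from blood instead of tissue:
low-coverage WGS read counts to copy-number profiles, tumor-fraction
estimation, a tumor-content scaling step, nearest-centroid CIN
classification, nucleosome-footprint scoring, targeted-methylation
scoring with on-treatment dynamics, and survival modelling. A synthetic
cohort generator with complete ground truth makes every stage testable;
the real patient data this design targets are controlled-access.

# Copy-number profiling

**Model.** Read counts per fixed-width genomic bin (default 500 kb) are
negative binomial with mean proportional to
`gc * (2 (1 - tf) + tf * CN) / 2`, the linear mixture of a diploid
non-tumor component and a tumor component with integer copy number `CN`.

**Reference panel.** `build_reference_panel()` depth-normalizes healthy
plasma profiles and stores the per-bin median (location) and MAD (scale).
Bins with zero median or relative MAD above 0.5 are blacklisted.
`normalize_profile()` reports per-bin `log2` ratios of the
depth-normalized sample against the panel location and re-anchors their
median at 0. The recentering matters: total-count normalization alone
shifts every ratio when aneuploidy moves mean ploidy away from 2, which
biases all downstream copy-number arithmetic; with at most ~35% of the
genome altered the median bin is copy-neutral and is the correct anchor.

**Segmentation.** `segment_profile()` recursively partitions each
chromosome. Each round evaluates both the best single boundary split and
the best interior window (window-versus-rest t statistic over all widths
up to 300 bins) and accepts the stronger candidate when its t statistic
exceeds `split_threshold` (default 5.0) with all parts at least
`min_segment_bins` (default 5) wide. The interior-window scan is the
essential part: a 30-bin single-copy event inside a 400-bin chromosome
produces a strong window statistic but a diluted boundary statistic, and
with boundary splits alone such events are missed stochastically — which
in turn aliases the tumor-fraction fit (below) to twice its true value on
near-diploid genomes. The threshold 5.0 keeps the per-genome false-split
rate negligible at the default noise level.

**Tumor fraction.** `estimate_tumor_fraction()` grid-searches
`tf` in steps of 0.01. At each candidate, every segment receives the
integer copy state in `{0, 1, 2, 3, 4}` whose expected ratio
`log2((2 (1 - tf) + tf CN) / 2)` is nearest its mean, and the bin-weighted
squared error selects the winner; near-ties resolve to the smallest `tf`.
Identifiability caveat: a genome containing only single-copy events fits
equally well at `2 tf` with two-copy states (and vice versa at `tf / 2`),
so the tie-break alone is not sufficient — reliable estimation needs both
one- and two-copy events detected, which the synthetic archetypes
guarantee and real CIN genomes typically provide. On the default cohort
the estimate recovers truth with RMSE below 0.01 for `tf` in 0.1–0.5.

# CIN classification and tumor-content scaling

Features are the segment-mean `log2` ratios averaged (bin-weighted) over
102 recurrent peak regions (43 amplifications, 59 deletions). Because
plasma dilutes every copy-number deviation by `tf`, profiles are first
rescaled to tumor-equivalent space:
`CN_obs = 2 * 2^L`, `L' = log2((2 + (CN_obs - 2) / tf) / 2)`, with `tf`
floored at 0.03 to cap noise amplification and the copy argument clipped
at 0.1 to keep `L'` finite. Scaling is done in linear copy-number space
because the dilution is linear in `CN`, not in `log2`.

`assign_cluster()` forces cluster 1 whenever the genome-altered fraction
(bins in segments with `|mean| > 0.1`) is below 0.05, and otherwise picks
the centroid with the highest Pearson correlation (scale-free, so
residual tumor-fraction miscalibration does not flip calls); ties go to
the lower cluster index. The burden guard is what the scaling step
rescues at low plasma tumor fraction: unscaled, a CIN-high genome at
plasma `tf <= 0.1` has all deviations below the calling threshold, the
burden reads ~0 and the sample is forced into cluster 1. On synthetic
paired cohorts with plasma `tf <= 0.1` the binary CIN-high/low accuracy
rises from roughly 40% unscaled to ~100% scaled, while cluster recovery
in tissue at `tf >= 0.3` is at least 95%.

For cohorts without matched tissue, `derive_cohort_scaling_factor()`
supplies the mean plasma/tissue tumor-fraction ratio of a reference
paired cohort in place of the per-sample ratio.

The real peak coordinates and centroids of the published classifier are
not public; the classifier is therefore parameterized by a peak/centroid
input, and the synthetic generator supplies self-consistent ones. Using
the package on real data requires externally supplied centroids.

# Nucleosome footprinting

`distance_profile()` histograms the signed distance from each fragment
start to the nearest nucleosome center (ties to the upstream center) in
10-bp bins over ±300 bp. Healthy cfDNA yields the characteristic M shape
— fragment starts avoid the protected core and pile up near ±73 bp —
while tumor-derived fragments are flatter and relatively enriched at the
center. `nucleosome_score()` projects a sample profile onto the
healthy-to-tumor axis, `score = <s-h, m-h> / <m-h, m-h>`, so the mean
healthy reference scores exactly 0 and the mean tumor reference exactly
1; out-of-range values are flagged, not truncated, since projection (not
clipping) is what makes the anchors exact. The score of a mixture sample
is linear in its mixture weight, which is the mechanism behind the strong
rank correlation between nucleosome scores and tumor fraction.

In the generator the mixture weight equals the plasma tumor fraction plus
Gaussian noise (sd 0.05); half of cluster-3 samples have the weight
damped by 0.35, reproducing the heterogeneous low/high score profile of
that cluster. This damping is why the nucleosome score is a poor CIN
classifier on its own (AUC ~0.7 against cluster 1 vs 2/3 on the default
cohort) even though it tracks its own generating weight almost perfectly.

# Targeted methylation

Target regions are selected to be nearly unmethylated in healthy plasma
(mean beta < 0.03) and hypermethylated in tumor, so the observed region
beta is again a linear mixture. `region_betas()` pools methylated /
unmethylated counts per region; `qc_filter()` retains samples with
bisulfite conversion at least 95% and mean region coverage at least 10x.

`train_score_model()` fits a 500-tree random forest (sqrt-features per
split, seeded) classifying baseline plasma against healthy reference
samples on raw region betas; baseline samples are scored out-of-bag. The
probability of the tumor class is the methylation score, 0 (healthy) to 1
(tumorigenic).

**Tumor-content normalization.** Two operations are provided.
`normalize_for_tumor_content()` inverts the beta mixture exactly,
`beta_t = (beta_obs - (1 - tf) beta_h) / tf` (clipped to [0, 1]), and is
the right tool for region-level questions. For *score deltas* between
baseline and on-treatment samples, however, beta-level renormalization is
the wrong input to a nonlinear forest readout: it rescales each sample's
noise by `tf_pre / tf_post` (up to ~2.5x here) and remaps the natural
point mass of zero betas to a nonzero constant, and the forest converts
those input-scale changes into score artifacts correlated with the
tumor-content change itself. The pipeline therefore normalizes on the
score scale: `tf_adjusted_delta()` fits
`delta ~ tf_change + tf_pre` across the cohort and removes the centered
fitted component, leaving deltas whose rank correlation with
tumor-content change is ~0 while preserving the cohort's overall shift
and the responder signal. `delta_stratify()` then splits patients at the
cohort median delta (recomputed per cohort, never hard-coded) into
"Large" versus "Small" methylation decrease groups.

# Survival and general statistics

`kaplan_meier()` is the product-limit estimator (median = earliest time
with survival at or below 0.5). `cox_fit()` maximizes the Cox partial
likelihood by Newton–Raphson with step halving and Breslow tie handling,
reporting Wald intervals; monotone likelihoods (a perfectly separating
term) are raised as errors rather than returned. `cox_multivariate()`
encodes the analysis defaults: primary group term (cluster 1 or the
"Large decrease" group as reference), age dichotomized at 65, gender, and
TNM stage as a categorical with an explicit missing level. Mann–Whitney
(exact when `min(n) <= 8` without ties), Spearman, ROC AUC
(Mann–Whitney formulation, ties at 1/2), a leave-one-out logistic score
combiner with ridge fallback under perfect separation, and the
at-least-one-subtype binomial sizing (`ceil(log(1-conf)/log(1-p))`;
29 patients at p = 0.1 and 95% confidence) complete the module. All
tests are two-sided with no multiplicity correction.

# The synthetic cohort: what it emulates, and what it does not

Defaults (all in `cohort_config()`): 74 patients, cluster probabilities
(0.1, 0.45, 0.45); tissue tumor fraction uniform on 0.1–0.5, halved for
cluster 1 (low-CIN tumors shed less DNA and their measured tumor
fractions are reported markedly lower); plasma tumor fraction exactly 0.6
of tissue; a 2.8-Gb genome of 14 chromosomes at 500-kb bins (~0.3x
coverage at the default 5.6M reads); negative-binomial dispersion
size = 2000 (~1.5x Poisson, the regime in which a held-out healthy
profile has mean |log2 ratio| < 0.05 against the panel, as for
well-behaved GC-corrected LC-WGS); archetype events of 26–40 bins for
single-copy changes and 12–20 bins for two-copy changes, clusters 2/3
sharing roughly half their events; methylation observation noise sd 0.04
per region (binomial sampling at moderate coverage) plus a per-individual
baseline offset (sd 0.01); responder probability 0.5 with a 0.15 drop in
tumor-component beta; survival in days, exponential baselines
(hazard 1/500 per day for OS) with hazard ratios 0.25 for CIN-high and
0.4 for large methylation decrease, ~20% independent censoring.

Problem sizes used by the test and acceptance suites — 100 samples for
tumor-fraction recovery, 30 paired samples for the scaling comparison, 45
for cluster recovery, 74 for nucleosome scoring, 100 for methylation,
2000 for Cox recovery — are the package's chosen design points for those
analyses.

Deliberate simplifications, and hence what passing tests do *not* show
about real data:

* No GC/mappability structure is simulated by default (a per-bin
  multiplicative factor is available); panel normalization is therefore
  easier than on real sequencing.
* The synthetic archetypes are cleanly separated and the depth favorable,
  so plasma/tissue concordance saturates near 100% where the motivating
  study reports 71% three-cluster agreement — the synthetic cohort
  demonstrates mechanism (scaling repairs low-tf calls), not the
  real-world error rate.
* Baseline methylation scores correlate strongly with tumor fraction here
  because the generator's signal is `tf * tumor_level`; in patients the
  reported correlation is weak, implying biology beyond tumor burden that
  the generator does not model.
* The measured methylation decrease groups recover true responders only
  partially (score ceiling near 1 compresses responder deltas), so the
  survival association with the *measured* groups is attenuated relative
  to the association with the generating truth at n = 74.
* Fragment simulation is positional only (no sequence, no fragment
  length); nucleosome centers are well-separated by construction so
  nearest-center assignment is unambiguous within the scoring window.

# Numerical conventions

Genomic intervals are 0-based half-open throughout (BED convention). Sex
chromosomes are not generated; on real data they should be excluded
before panel construction. Medians of even-length sets are the mean of
the central order statistics. All generators and the forest are
deterministic under `cohort_config(seed = )`; `run_report()` is
byte-reproducible given its configuration.
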