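# cfcin — CIN stratification of metastatic colorectal cancer from plasma cfDNA

`cfcin` is an R package plus analysis workflow for stratifying metastatic
colorectal cancer (mCRC) patients into chromosomal-instability (CIN)
clusters from low-coverage whole-genome sequencing (LC-WGS) of plasma
cell-free DNA, and for relating those clusters — together with nucleosome
footprints and targeted methylation dynamics — to outcome under
bevacizumab-based therapy. It is written for computational biologists who
need the full liquid-biopsy chain testable end to end: the real cohorts
this design targets are controlled-access, so the package ships a
synthetic paired tissue/plasma cohort generator with complete ground
truth, and every stage is validated against it.

## The model

Plasma cfDNA is a two-component mixture. With tumor fraction *tf* and
tumor copy number *CN* in a bin, the expected depth-normalized coverage is

    E[coverage] ∝ (2 (1 − tf) + tf · CN) / 2

Binned counts are normalized against a healthy reference panel
(median/MAD per bin, median-recentered log2 ratios), segmented by
recursive splitting with interior-window scans (CBS-style), and the tumor
fraction is estimated by a grid search that assigns each segment an
integer copy state and minimizes the bin-weighted squared error — smallest
*tf* wins near-ties, guarding against purity/ploidy aliasing.

Because every deviation in plasma is diluted by *tf*, profiles are
rescaled to tumor-equivalent space before classification:

    CN_obs = 2 · 2^L ,   L' = log2( (2 + (CN_obs − 2)/tf) / 2 )

A sample is assigned CIN cluster 1/2/3 by a burden guard (genome-altered
fraction < 0.05 forces cluster 1) followed by nearest-centroid Pearson
correlation over 102 recurrent peak regions (43 amplifications, 59
deletions). Companion modules compute the nucleosome-footprint deviation
score (projection of the fragment-start distance profile onto the
healthy→tumor axis, 0 = healthy, 1 = tumor), region-level bisulfite
methylation scores (random-forest probability, tumor vs healthy), score
deltas under therapy adjusted for tumor-content change, and
Kaplan–Meier / multivariate Cox survival analyses (Breslow ties).

## Worked example

```r
library(cfcin)

cfg    <- cohort_config(seed = 1)            # 74 patients, defaults
cohort <- simulate_cohort(cfg)

panel  <- build_reference_panel(cohort$healthy_profiles)
plasma <- profile_cohort(cohort$plasma_profiles, panel)

# tumor fraction of the first plasma sample
plasma[[1]]$tf$tf
#> [1] 0.09
cohort$truth$tf_plasma[1]
#> [1] 0.1040096

# classify it into a CIN cluster (scaling for tumor content first)
classify_cin_sample(plasma[[1]]$seg, plasma[[1]]$tf$tf,
                    cohort$peaks, cohort$centroids)$cluster
#> [1] 2
cohort$truth$cluster[1]
#> [1] 2
```

The numbered drivers under `analysis/` run the whole study on the default
synthetic cohort and narrate what they find (tables land in
`results/analysis/`). For example, `analysis/03_cin_classification.R`
prints the package's central comparison — tumor-content scaling repairs
plasma classification:

```
plasma vs tissue concordance, scaled: match 100.0%, binary 100.0%
plasma vs tissue concordance, unscaled: match 89.2%, binary 89.2%
truth recovery: tissue 100.0%, plasma scaled 100.0%, plasma raw 89.2%
cohort plasma/tissue scaling factor: 0.592 (generator: 0.60)
```

and `analysis/06_survival.R` the outcome analysis by plasma CIN cluster
(hazard ratios below 1 mean longer survival than cluster 1):

```
KM median, CIN-low 492 d vs CIN-high 1965 d
Cox by plasma CIN cluster (reference: cluster 1):
  cluster2               HR 0.23 (95% CI 0.09-0.60) p = 0.0028
  cluster3               HR 0.22 (95% CI 0.08-0.61) p = 0.00326
```

Run them in order:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

The methods vignette (`vignettes/cfcin-methods.Rmd`) documents the model,
every tunable default, and what the synthetic cohort does and does not
emulate.

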