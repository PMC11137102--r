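#!/usr/bin/env Rscript
# Copy-number profiling of the cohort: build the healthy reference panel,
# normalize and segment every tissue and plasma sample, and estimate
# per-sample tumor fractions. Writes the tumor-fraction table the later
# scripts consume.

source("analysis/00_common.R")

cohort <- get_cohort()
truth <- cohort$truth

panel <- build_reference_panel(cohort$healthy_profiles)
msg("reference panel: %d healthy samples, %d/%d bins blacklisted",
    length(panel$sample_ids), sum(panel$blacklist), nrow(panel$bins))

tissue <- profile_cohort(cohort$tissue_profiles, panel)
plasma <- profile_cohort(cohort$plasma_profiles, panel)

tf <- data.frame(
  patient_id = truth$patient_id,
  tf_tissue_true = truth$tf_tissue,
  tf_tissue_hat = vapply(tissue, function(x) x$tf$tf, numeric(1)),
  tf_plasma_true = truth$tf_plasma,
  tf_plasma_hat = vapply(plasma, function(x) x$tf$tf, numeric(1)),
  burden_tissue = vapply(tissue, function(x) x$seg$genome_altered_fraction,
                         numeric(1)),
  burden_plasma = vapply(plasma, function(x) x$seg$genome_altered_fraction,
                         numeric(1)),
  n_segments_plasma = vapply(plasma, function(x) nrow(x$seg$segments),
                             numeric(1)))
write_tsv(tf, file.path(RESULTS_DIR, "tumor_fractions.tsv"))

msg("tumor-fraction recovery: tissue RMSE %.4f, plasma RMSE %.4f",
    sqrt(mean((tf$tf_tissue_hat - tf$tf_tissue_true)^2)),
    sqrt(mean((tf$tf_plasma_hat - tf$tf_plasma_true)^2)))
msg("Spearman rho (tissue) = %.3f",
    spearman_cor(tf$tf_tissue_hat, tf$tf_tissue_true)$rho)

# plasma tumor fractions are lower than tissue, and cluster 1 lower still:
# the two premises behind tumor-content scaling
mw <- mann_whitney(tf$tf_plasma_hat[truth$cluster == 1],
                   tf$tf_plasma_hat[truth$cluster != 1])
msg("plasma tf, cluster 1 vs 2/3: U = %.0f, p = %.3g %s",
    mw$U, mw$p, signif_stars(mw$p))

# example segment tables for one plasma sample
write_bed(plasma[[1]]$seg$segments[, c("chrom", "start", "end", "mean_lr",
                                       "n_bins")],
          file.path(RESULTS_DIR, "example_plasma_segments.bed"))
msg("tables written to %s", RESULTS_DIR)
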