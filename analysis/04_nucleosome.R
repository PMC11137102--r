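#!/usr/bin/env Rscript
# Nucleosome footprinting: the M-shaped distance profile, the 0-1
# deviation score, its relation to tumor fraction, and its (weak) value as
# a CIN-cluster classifier on its own and combined with the methylation
# score by logistic regression.

source("analysis/00_common.R")

cohort <- get_cohort()
truth <- cohort$truth
track <- cohort$nucleosome$track

profiles <- lapply(cohort$nucleosome$fragments, distance_profile,
                   track = track)
refs <- reference_profiles(
  lapply(cohort$nucleosome$healthy_ref_fragments, distance_profile,
         track = track),
  lapply(cohort$nucleosome$tumor_ref_fragments, distance_profile,
         track = track))

center <- which(refs$healthy$mid == 5)
msg("healthy reference central fraction %.4f vs tumor %.4f (M-shape dip)",
    refs$healthy$fraction[center], refs$tumor$fraction[center])

scores <- vapply(profiles, function(p)
  nucleosome_score(p, refs$healthy, refs$tumor)$score, numeric(1))
rho_w <- score_tf_correlation(scores, truth$nf_weight)
rho_tf <- score_tf_correlation(scores, truth$tf_plasma)
msg("score vs generating mixture weight: rho = %.3f (p = %.2g)",
    rho_w$rho, rho_w$p)
msg("score vs plasma tumor fraction:     rho = %.3f (p = %.2g)",
    rho_tf$rho, rho_tf$p)

# cluster-wise score comparisons (cluster 3 is heterogeneous by design)
for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
  mw <- mann_whitney(scores[truth$cluster == pair[1]],
                     scores[truth$cluster == pair[2]])
  msg("nucleosome score cluster %d vs %d: p = %.3g %s",
      pair[1], pair[2], mw$p, signif_stars(mw$p))
}
auc_nf <- roc_auc(scores, truth$cluster %in% 2:3)
msg("nucleosome score alone, CIN-high vs low: AUC = %.2f", auc_nf)

# reference profile export
write_tsv(data.frame(bin_low = refs$healthy$breaks[-length(refs$healthy$breaks)],
                     bin_high = refs$healthy$breaks[-1],
                     healthy = refs$healthy$fraction,
                     tumor = refs$tumor$fraction),
          file.path(RESULTS_DIR, "nucleosome_reference_profiles.tsv"))
write_tsv(data.frame(patient_id = truth$patient_id,
                     nucleosome_score = scores,
                     nf_weight = truth$nf_weight,
                     cluster = truth$cluster),
          file.path(RESULTS_DIR, "nucleosome_scores.tsv"))
msg("tables written to %s", RESULTS_DIR)
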