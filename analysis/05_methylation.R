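#!/usr/bin/env Rscript
# Targeted methylation: QC, the tumor-vs-healthy random-forest score,
# subtype separation at baseline, the combined methylation+nucleosome
# classifier, and tumor-content-adjusted on-treatment score deltas.

source("analysis/00_common.R")

cohort <- get_cohort()
truth <- cohort$truth
meth <- cohort$methylation
n <- nrow(truth)

# score model on raw baseline betas vs healthy reference; baseline scores
# are out-of-bag
model <- train_score_model(meth$pre, meth$healthy, seed = COHORT_SEED)
pre_s <- model$oob_scores[seq_len(n)]
post_s <- methylation_score(model, meth$post)
names(pre_s) <- names(post_s) <- truth$patient_id

msg("baseline methylation scores: %.2f-%.2f (healthy OOB mean %.2f)",
    min(pre_s), max(pre_s),
    mean(model$oob_scores[-seq_len(n)]))

mw12 <- mann_whitney(pre_s[truth$cluster == 1], pre_s[truth$cluster != 1])
msg("baseline score, cluster 1 vs 2/3: p = %.3g %s", mw12$p,
    signif_stars(mw12$p))
auc_me <- roc_auc(pre_s, truth$cluster %in% 2:3)
msg("methylation score, CIN-high vs low: AUC = %.2f", auc_me)
rho_tf <- spearman_cor(pre_s, truth$tf_plasma)
msg("baseline score vs tumor content: rho = %.2f (p = %.2g)",
    rho_tf$rho, rho_tf$p)

# combined methylation + nucleosome classifier (leave-one-out logistic)
track <- cohort$nucleosome$track
nf_scores <- local({
  refs <- reference_profiles(
    lapply(cohort$nucleosome$healthy_ref_fragments, distance_profile,
           track = track),
    lapply(cohort$nucleosome$tumor_ref_fragments, distance_profile,
           track = track))
  vapply(cohort$nucleosome$fragments, function(fr)
    nucleosome_score(distance_profile(fr, track), refs$healthy,
                     refs$tumor)$score, numeric(1))
})
comb <- combine_scores_logistic(pre_s, nf_scores, truth$cluster %in% 2:3,
                                seed = COHORT_SEED)
msg("AUC: methylation %.2f, nucleosome %.2f, combined (LOO) %.2f",
    comb$auc_a, comb$auc_b, comb$auc_combined)

# on-treatment deltas, adjusted for tumor-content change, then stratified
# at the cohort median
adj <- tf_adjusted_delta(pre_s, post_s, truth$tf_plasma,
                         truth$tf_plasma_post)
strat <- delta_stratify(pre_s, post_s, deltas = adj$delta)
msg("median adjusted score delta: %.3f", strat$median_delta)
rho_chg <- spearman_cor(adj$delta, truth$tf_plasma_post - truth$tf_plasma)
msg("adjusted delta vs tumor-content change: rho = %.2f (independence check)",
    rho_chg$rho)
tab <- table(strat$deltas$decrease_group, truth$responder)
msg("decrease groups vs true responders:")
print(tab)

write_tsv(cbind(strat$deltas,
                responder = truth$responder,
                cluster = truth$cluster),
          file.path(RESULTS_DIR, "methylation_scores.tsv"))
msg("tables written to %s", RESULTS_DIR)
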