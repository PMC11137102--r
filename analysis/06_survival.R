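#!/usr/bin/env Rscript
# Outcome analyses: Kaplan-Meier and multivariate Cox regression of OS and
# PFS by plasma CIN cluster and by methylation decrease group, adjusted
# for age, gender and TNM stage.

source("analysis/00_common.R")

cohort <- get_cohort()
truth <- cohort$truth
panel <- build_reference_panel(cohort$healthy_profiles)
plasma <- profile_cohort(cohort$plasma_profiles, panel)
n <- nrow(truth)

plasma_cluster <- vapply(seq_len(n), function(i)
  classify_cin_sample(plasma[[i]]$seg, plasma[[i]]$tf$tf, cohort$peaks,
                      cohort$centroids)$cluster, integer(1))

# methylation decrease groups (as in analysis/05)
meth <- cohort$methylation
model <- train_score_model(meth$pre, meth$healthy, seed = COHORT_SEED)
pre_s <- model$oob_scores[seq_len(n)]
post_s <- methylation_score(model, meth$post)
names(pre_s) <- names(post_s) <- truth$patient_id
adj <- tf_adjusted_delta(pre_s, post_s, truth$tf_plasma,
                         truth$tf_plasma_post)
strat <- delta_stratify(pre_s, post_s, deltas = adj$delta)

report_cox <- function(fit, label) {
  if (inherits(fit, "cox_fit")) {
    for (i in seq_along(fit$hr))
      msg("  %-22s HR %.2f (95%% CI %.2f-%.2f) p = %.3g", names(fit$hr)[i],
          fit$hr[i], fit$ci_lower[i], fit$ci_upper[i], fit$p[i])
  } else msg("  %s: %s", label, fit)
}

for (endpoint in c("os", "pfs")) {
  tt <- truth[[paste0(endpoint, "_time")]]
  ee <- truth[[paste0(endpoint, "_event")]]
  rec <- data.frame(time = tt, event = ee,
                    cluster = factor(plasma_cluster),
                    decrease_group = strat$deltas$decrease_group,
                    age = truth$age, gender = truth$gender,
                    tnm_stage = truth$tnm_stage)
  msg("== %s ==", toupper(endpoint))
  km <- kaplan_meier(tt, ee, ifelse(plasma_cluster == 1, "CIN-low", "CIN-high"))
  msg("KM median, CIN-low %.0f d vs CIN-high %.0f d",
      km[["CIN-low"]]$median, km[["CIN-high"]]$median)
  msg("Cox by plasma CIN cluster (reference: cluster 1):")
  report_cox(tryCatch(cox_multivariate(rec, "cluster", ref = "1"),
                      error = function(e) conditionMessage(e)), "cluster")
  kmd <- kaplan_meier(tt, ee, strat$deltas$decrease_group)
  msg("KM median, Large decrease %.0f d vs Small %.0f d",
      kmd$Large$median, kmd$Small$median)
  msg("Cox by methylation decrease group (reference: Large decrease):")
  report_cox(tryCatch(cox_multivariate(rec, "decrease_group", ref = "Large"),
                      error = function(e) conditionMessage(e)), "decrease")
}

surv_df <- data.frame(patient_id = truth$patient_id,
                      os_time = truth$os_time, os_event = truth$os_event,
                      pfs_time = truth$pfs_time, pfs_event = truth$pfs_event,
                      plasma_cluster = plasma_cluster,
                      decrease_group = strat$deltas$decrease_group)
write_tsv(surv_df, file.path(RESULTS_DIR, "survival_groups.tsv"))
msg("tables written to %s", RESULTS_DIR)
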