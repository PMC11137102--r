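# Cohort-level orchestration: chain panel building, normalization,
# segmentation, tumor-fraction estimation and CIN classification over a
# cohort, and produce a machine-readable end-to-end report. No statistic is
# computed here that is not a module operation.

#' Normalize, segment and estimate tumor fraction for a list of profiles
#'
#' @param profiles List of `binned_coverage_profile`s.
#' @param panel A `reference_panel`.
#' @param min_segment_bins,split_threshold,calling_threshold Segmentation
#'   controls (see [segment_profile()]).
#' @param tf_grid,cn_states Tumor-fraction fit controls (see
#'   [estimate_tumor_fraction()]).
#' @return List per sample: `seg` (`segmented_cna_profile`) and `tf`
#'   (`tumor_fraction_estimate`).
#' @export
profile_cohort <- function(profiles, panel, min_segment_bins = 5,
                           split_threshold = 5, calling_threshold = 0.1,
                           tf_grid = seq(0, 1, by = 0.01), cn_states = 0:4) {
  lapply(profiles, function(p) {
    lrp <- normalize_profile(p, panel)
    seg <- segment_profile(lrp, min_segment_bins = min_segment_bins,
                           split_threshold = split_threshold,
                           calling_threshold = calling_threshold)
    list(seg = seg, tf = estimate_tumor_fraction(seg, tf_grid = tf_grid,
                                                 cn_states = cn_states))
  })
}

#' Classify one segmented profile into a CIN cluster
#'
#' Optionally rescales the profile for tumor content first (the scaling
#' procedure that compensates dilution of tumor DNA in plasma), then
#' extracts peak features and assigns the nearest-centroid cluster with
#' the burden guard.
#'
#' @param seg A `segmented_cna_profile`.
#' @param tf Tumor fraction used for scaling (per-sample estimate, or a
#'   cohort scaling factor for cohorts without matched tissue).
#' @param peaks,centroids Peak region set and cluster centroids.
#' @param scale Apply tumor-content scaling first?
#' @param floor_tf,burden_threshold See
#'   [scale_profile_for_tumor_fraction()] and [assign_cluster()].
#' @return A `cluster_assignment`.
#' @export
classify_cin_sample <- function(seg, tf, peaks, centroids, scale = TRUE,
                                floor_tf = 0.03, burden_threshold = 0.05) {
  if (scale)
    seg <- scale_profile_for_tumor_fraction(seg, tf, floor_tf = floor_tf)
  fv <- extract_peak_features(seg, peaks)
  assign_cluster(fv, centroids, seg$genome_altered_fraction,
                 burden_threshold = burden_threshold)
}

#' Run the full pipeline on a (simulated) cohort and write a report
#'
#' Generates a synthetic cohort from `config`, runs every stage — healthy
#' reference panel, log-ratio profiles, segmentation, tumor fractions,
#' tumor-content scaling, CIN cluster assignment in tissue and plasma,
#' plasma/tissue concordance, nucleosome scoring, methylation QC +
#' scoring + delta stratification, and survival analyses — and writes
#' per-sample TSV tables plus a JSON summary under `out_dir`. Everything
#' is deterministic given `config$seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()].
#' @return The summary list, invisibly.
#' @export
run_report <- function(out_dir, config = cohort_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  truth <- cohort$truth
  n <- nrow(truth)

  panel <- build_reference_panel(cohort$healthy_profiles)
  tissue <- profile_cohort(cohort$tissue_profiles, panel)
  plasma <- profile_cohort(cohort$plasma_profiles, panel)
  tf_tissue_hat <- vapply(tissue, function(x) x$tf$tf, numeric(1))
  tf_plasma_hat <- vapply(plasma, function(x) x$tf$tf, numeric(1))

  assign_one <- function(fits, tfs) lapply(seq_len(n), function(i) {
    a <- classify_cin_sample(fits[[i]]$seg, tfs[i], cohort$peaks,
                             cohort$centroids)
    a$sample_id <- truth$patient_id[i]
    a
  })
  tissue_assign <- assign_one(tissue, tf_tissue_hat)
  plasma_assign <- assign_one(plasma, tf_plasma_hat)
  plasma_unscaled <- lapply(seq_len(n), function(i) {
    a <- classify_cin_sample(plasma[[i]]$seg, tf_plasma_hat[i], cohort$peaks,
                             cohort$centroids, scale = FALSE)
    a$sample_id <- truth$patient_id[i]
    a
  })
  conc <- concordance(plasma_assign, tissue_assign)
  conc_unscaled <- concordance(plasma_unscaled, tissue_assign)
  scaling_factor <- derive_cohort_scaling_factor(pmax(tf_tissue_hat, 1e-3),
                                                 tf_plasma_hat)

  # nucleosome scoring
  prof <- lapply(cohort$nucleosome$fragments, distance_profile,
                 track = cohort$nucleosome$track)
  refs <- reference_profiles(
    lapply(cohort$nucleosome$healthy_ref_fragments, distance_profile,
           track = cohort$nucleosome$track),
    lapply(cohort$nucleosome$tumor_ref_fragments, distance_profile,
           track = cohort$nucleosome$track))
  nf_scores <- vapply(prof, function(p)
    nucleosome_score(p, refs$healthy, refs$tumor)$score, numeric(1))
  nf_tf_cor <- score_tf_correlation(nf_scores, tf_plasma_hat)
  nf_weight_cor <- score_tf_correlation(nf_scores, truth$nf_weight)

  # methylation: train the tumor-vs-healthy forest on raw baseline betas
  # (scores are out-of-bag for those), score raw on-treatment betas, then
  # normalize the per-patient score change for the treatment-induced drop
  # in circulating tumor content, so the stratification reflects
  # methylation dynamics rather than tumor-fraction dynamics
  meth <- cohort$methylation
  model <- train_score_model(meth$pre, meth$healthy, seed = config$seed)
  pre_scores <- model$oob_scores[seq_len(n)]
  post_scores <- methylation_score(model, meth$post)
  names(pre_scores) <- names(post_scores) <- truth$patient_id
  adj <- tf_adjusted_delta(pre_scores, post_scores,
                           truth$tf_plasma, truth$tf_plasma_post)
  strat <- delta_stratify(pre_scores, post_scores, deltas = adj$delta)
  meth_auc <- roc_auc(pre_scores, truth$cluster %in% c(2, 3))
  nf_auc <- roc_auc(nf_scores, truth$cluster %in% c(2, 3))

  # survival by plasma CIN cluster and by methylation decrease group
  plasma_cluster <- vapply(plasma_assign, `[[`, integer(1), "cluster")
  os <- data.frame(time = truth$os_time, event = truth$os_event,
                   cluster = factor(plasma_cluster),
                   decrease_group = strat$deltas$decrease_group,
                   age = truth$age, gender = truth$gender,
                   tnm_stage = truth$tnm_stage)
  km_cluster <- kaplan_meier(os$time, os$event,
                             ifelse(plasma_cluster == 1, "CIN-low", "CIN-high"))
  cox_cluster <- tryCatch(cox_multivariate(os, "cluster", ref = "1"),
                          error = function(e) e$message)
  cox_meth <- tryCatch(cox_multivariate(os, "decrease_group", ref = "Large"),
                       error = function(e) e$message)

  samples <- data.frame(
    patient_id = truth$patient_id,
    true_cluster = truth$cluster,
    tf_tissue_true = truth$tf_tissue, tf_tissue_hat = tf_tissue_hat,
    tf_plasma_true = truth$tf_plasma, tf_plasma_hat = tf_plasma_hat,
    tissue_cluster = vapply(tissue_assign, `[[`, integer(1), "cluster"),
    plasma_cluster = plasma_cluster,
    plasma_cluster_unscaled = vapply(plasma_unscaled, `[[`, integer(1), "cluster"),
    nucleosome_score = nf_scores,
    meth_score_pre = as.numeric(pre_scores),
    meth_score_post = as.numeric(post_scores),
    meth_delta = strat$deltas$delta,
    decrease_group = strat$deltas$decrease_group)
  write_tsv(samples, file.path(out_dir, "samples.tsv"))
  write_tsv(as.data.frame(conc$confusion), file.path(out_dir, "confusion.tsv"))

  summary <- list(
    n_patients = n,
    seed = config$seed,
    concordance = list(match_rate = conc$match_rate,
                       binary_accuracy = conc$binary_accuracy,
                       confusion = conc$confusion),
    concordance_unscaled = list(match_rate = conc_unscaled$match_rate,
                                binary_accuracy = conc_unscaled$binary_accuracy),
    cohort_scaling_factor = scaling_factor,
    tf_rmse_tissue = sqrt(mean((tf_tissue_hat - truth$tf_tissue)^2)),
    nucleosome_tf_rho = nf_tf_cor$rho,
    nucleosome_weight_rho = nf_weight_cor$rho,
    auc_methylation_vs_cin = meth_auc,
    auc_nucleosome_vs_cin = nf_auc,
    median_meth_delta = strat$median_delta,
    km_median_cin_high = km_cluster[["CIN-high"]]$median,
    km_median_cin_low = km_cluster[["CIN-low"]]$median,
    cox_cluster = if (inherits(cox_cluster, "cox_fit"))
      list(hr = cox_cluster$hr, p = cox_cluster$p) else cox_cluster,
    cox_decrease = if (inherits(cox_meth, "cox_fit"))
      list(hr = cox_meth$hr, p = cox_meth$p) else cox_meth)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
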