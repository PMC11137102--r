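# Targeted bisulfite methylation: region-level betas, sample QC,
# tumor-content deconvolution, a random-forest tumorigenicity score, and
# stratification by on-treatment score change.

#' Region-level beta values from methylated/unmethylated counts
#'
#' `beta = meth / (meth + unmeth)` per sample x region; zero-coverage
#' cells are missing. Counts for the same sample/region (e.g. per-CpG
#' rows) are pooled before the ratio is taken.
#'
#' @param counts Data frame with columns `sample`, `region_id`, `meth`,
#'   `unmeth` (non-negative).
#' @return List of class `"methylation_matrix"`: `beta` (samples x
#'   regions), `coverage` (total reads per cell).
#' @export
region_betas <- function(counts) {
  stopifnot(all(c("sample", "region_id", "meth", "unmeth") %in% names(counts)))
  if (any(counts$meth < 0) || any(counts$unmeth < 0))
    stop("methylation counts must be non-negative")
  meth <- tapply(counts$meth, list(counts$sample, counts$region_id), sum)
  unmeth <- tapply(counts$unmeth, list(counts$sample, counts$region_id), sum)
  meth[is.na(meth)] <- 0; unmeth[is.na(unmeth)] <- 0
  cov <- meth + unmeth
  beta <- ifelse(cov > 0, meth / cov, NA_real_)
  structure(list(beta = beta, coverage = cov), class = "methylation_matrix")
}

#' Sample quality filter for targeted bisulfite sequencing
#'
#' A sample passes when its bisulfite conversion rate is at least
#' `min_conversion` (default 95%) and its mean coverage over the captured
#' regions is at least `min_coverage` (default 10x).
#'
#' @param records Data frame with columns `sample_id`,
#'   `bisulfite_conversion_rate` (in \[0, 1\]) and `mean_region_coverage`.
#' @param min_conversion,min_coverage QC thresholds.
#' @return List: `records` (input plus `pass` and `fail_reason`),
#'   `retained` (passing sample ids), `n_retained`, `n_excluded`,
#'   `exclusions` (counts per fail reason).
#' @export
qc_filter <- function(records, min_conversion = 0.95, min_coverage = 10) {
  stopifnot(all(c("sample_id", "bisulfite_conversion_rate",
                  "mean_region_coverage") %in% names(records)))
  if (anyDuplicated(records$sample_id))
    stop("one QC record per sample required")
  conv_ok <- records$bisulfite_conversion_rate >= min_conversion
  cov_ok <- records$mean_region_coverage >= min_coverage
  reason <- rep(NA_character_, nrow(records))
  reason[!conv_ok] <- "conversion"
  reason[conv_ok & !cov_ok] <- "coverage"
  records$pass <- conv_ok & cov_ok
  records$fail_reason <- reason
  list(records = records,
       retained = records$sample_id[records$pass],
       n_retained = sum(records$pass),
       n_excluded = sum(!records$pass),
       exclusions = table(reason[!is.na(reason)]))
}

#' Deconvolve observed betas to the tumor component
#'
#' Under the two-component mixture
#' `beta_obs = (1 - tf) * beta_healthy + tf * beta_tumor`, the
#' tumor-component beta is
#' `beta_t = (beta_obs - (1 - tf) * beta_healthy) / tf`, clipped to
#' \[0, 1\]. This is how on-treatment methylation values are normalized
#' for the tumor content of each plasma sample, so score changes reflect
#' methylation dynamics rather than shifts in circulating tumor DNA.
#'
#' @param beta_obs Observed betas (vector or samples x regions matrix).
#' @param beta_healthy_ref Per-region healthy reference beta (recycled
#'   along rows of a matrix).
#' @param tf Tumor fraction(s), one per sample; values below `floor_tf`
#'   are clipped to `floor_tf`.
#' @param floor_tf Lower clip bounding noise amplification.
#' @return Tumor-component betas, same shape as `beta_obs`.
#' @export
normalize_for_tumor_content <- function(beta_obs, beta_healthy_ref, tf,
                                        floor_tf = 0.03) {
  tf <- pmax(tf, floor_tf)
  if (any(!is.finite(tf)) || any(tf <= 0))
    stop("tumor fraction must be positive")
  if (is.matrix(beta_obs)) {
    stopifnot(length(tf) %in% c(1L, nrow(beta_obs)))
    h <- matrix(beta_healthy_ref, nrow(beta_obs), ncol(beta_obs), byrow = TRUE)
    bt <- (beta_obs - (1 - tf) * h) / tf
  } else {
    bt <- (beta_obs - (1 - tf) * beta_healthy_ref) / tf
  }
  bt[bt < 0] <- 0
  bt[bt > 1] <- 1
  bt
}

#' Re-express betas at a reference tumor content
#'
#' Deconvolves observed betas to the tumor component at the sample's own
#' tumor fraction (see [normalize_for_tumor_content()]) and remixes them at
#' a reference tumor fraction:
#' `beta' = (1 - tf_target) * beta_healthy + tf_target * beta_tumor`.
#' This is how on-treatment methylation values are put on the same
#' tumor-content scale as the baseline sample, so that score changes
#' between timepoints reflect methylation dynamics rather than the drop in
#' circulating tumor DNA that treatment itself causes.
#'
#' The two steps collapse algebraically to
#' `beta' = beta_healthy + (tf_target / tf) * (beta_obs - beta_healthy)`,
#' clipped to \[0, 1\] only once at the end: materializing the intermediate tumor-component betas would
#' amplify region-level noise by `1 / tf` (large at low tumor content) and
#' clip it asymmetrically, biasing the adjusted values in a
#' tumor-content-dependent way. Fused, the noise is only rescaled by
#' `tf_target / tf`.
#'
#' @inheritParams normalize_for_tumor_content
#' @param tf_target Tumor fraction(s) to remix at (typically the baseline
#'   tumor fraction of the same patient).
#' @return Adjusted betas, same shape as `beta_obs`.
#' @export
renormalize_tumor_content <- function(beta_obs, beta_healthy_ref, tf,
                                      tf_target, floor_tf = 0.03) {
  tf <- pmax(tf, floor_tf)
  tf_target <- pmax(tf_target, floor_tf)
  if (any(!is.finite(tf)) || any(tf <= 0)) stop("tumor fraction must be positive")
  if (is.matrix(beta_obs)) {
    stopifnot(length(tf) %in% c(1L, nrow(beta_obs)),
              length(tf_target) %in% c(1L, nrow(beta_obs)))
    h <- matrix(beta_healthy_ref, nrow(beta_obs), ncol(beta_obs), byrow = TRUE)
  } else {
    h <- beta_healthy_ref
  }
  adj <- h + (tf_target / tf) * (beta_obs - h)
  adj[adj < 0] <- 0
  adj[adj > 1] <- 1
  adj
}

#' Train the tumor-vs-healthy methylation score model
#'
#' A random forest on region betas, classifying tumor (pre-treatment
#' plasma) against healthy reference samples. Scores for the training
#' samples themselves are taken out-of-bag so no sample is scored by trees
#' that saw it. Training is reproducible given `seed`.
#'
#' @param tumor_betas,healthy_betas Matrices (samples x regions), at least
#'   5 rows each, identical region sets.
#' @param n_trees,mtry Forest size and features per split (`mtry = NULL`
#'   gives the square-root default).
#' @param seed Integer seed.
#' @return List of class `"methylation_score_model"`: `forest`,
#'   `oob_scores` (tumor then healthy training rows), `regions`,
#'   `healthy_ref` (per-region healthy mean used for imputation), `seed`.
#' @export
train_score_model <- function(tumor_betas, healthy_betas, n_trees = 500,
                              mtry = NULL, seed = 1L) {
  if (is.null(tumor_betas) || is.null(healthy_betas) ||
      nrow(tumor_betas) < 5 || nrow(healthy_betas) < 5)
    stop("need at least 5 samples per class")
  stopifnot(identical(colnames(tumor_betas), colnames(healthy_betas)))
  X <- rbind(tumor_betas, healthy_betas)
  y <- factor(c(rep("tumor", nrow(tumor_betas)),
                rep("healthy", nrow(healthy_betas))),
              levels = c("healthy", "tumor"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                       mtry = mtry)
  oob <- forest$votes[, "tumor"]   # vote fractions are out-of-bag
  structure(list(forest = forest, oob_scores = as.numeric(oob),
                 regions = colnames(X),
                 healthy_ref = colMeans(healthy_betas), seed = seed),
            class = "methylation_score_model")
}

#' Score a sample's methylation profile
#'
#' Random-forest probability that the profile is tumor-like, from 0
#' (healthy) to 1 (tumorigenic). Missing regions are imputed with the
#' healthy reference mean and flagged; more than 50% missing is refused.
#'
#' @param model A `methylation_score_model`.
#' @param betas Numeric vector (named by region) or samples x regions
#'   matrix.
#' @return Numeric score(s) in \[0, 1\]; attribute `n_imputed` gives the
#'   number of imputed regions.
#' @export
methylation_score <- function(model, betas) {
  if (!is.matrix(betas)) betas <- matrix(betas, 1,
                                         dimnames = list(NULL, names(betas)))
  if (!is.null(colnames(betas))) {
    missing_regions <- setdiff(model$regions, colnames(betas))
    full <- matrix(NA_real_, nrow(betas), length(model$regions),
                   dimnames = list(rownames(betas), model$regions))
    full[, intersect(colnames(betas), model$regions)] <-
      betas[, intersect(colnames(betas), model$regions), drop = FALSE]
    betas <- full
  } else {
    stopifnot(ncol(betas) == length(model$regions))
    colnames(betas) <- model$regions
  }
  n_imp <- sum(is.na(betas))
  frac_missing <- rowMeans(is.na(betas))
  if (any(frac_missing > 0.5))
    stop("more than 50% of regions missing for ",
         sum(frac_missing > 0.5), " sample(s)")
  for (j in seq_len(ncol(betas))) {
    nas <- is.na(betas[, j])
    if (any(nas)) betas[nas, j] <- model$healthy_ref[j]
  }
  p <- stats::predict(model$forest, betas, type = "prob")[, "tumor"]
  structure(as.numeric(p), n_imputed = n_imp)
}

#' Adjust methylation score deltas for tumor-content change
#'
#' Treatment reduces the amount of circulating tumor DNA, which by itself
#' moves the methylation score down regardless of any methylation change.
#' This removes the cohort-level dependence of the raw score delta
#' (`post - pre`) on the tumor-fraction change (and baseline tumor
#' fraction): a linear model `delta ~ tf_change + tf_pre` is fitted across
#' the cohort and its centered fitted component subtracted, so the
#' adjusted deltas carry the same overall median shift but are
#' uncorrelated with tumor-content dynamics.
#'
#' @param pre_scores,post_scores Per-patient methylation scores at baseline
#'   and on-treatment.
#' @param tf_pre,tf_post Per-patient tumor fractions at the two timepoints.
#' @return List: `delta` (adjusted deltas, named like `pre_scores`),
#'   `raw_delta`, `fit` (the adjustment model).
#' @export
tf_adjusted_delta <- function(pre_scores, post_scores, tf_pre, tf_post) {
  n <- length(pre_scores)
  stopifnot(length(post_scores) == n, length(tf_pre) == n,
            length(tf_post) == n)
  if (n < 4) stop("need at least 4 patients to fit the adjustment")
  raw <- as.numeric(post_scores) - as.numeric(pre_scores)
  tfc <- tf_post - tf_pre
  fit <- stats::lm(raw ~ tfc + tf_pre)
  adj <- raw - (stats::fitted(fit) - mean(stats::fitted(fit)))
  names(adj) <- names(pre_scores)
  list(delta = adj, raw_delta = stats::setNames(raw, names(pre_scores)),
       fit = fit)
}

#' Stratify patients by on-treatment methylation score change
#'
#' `delta = post - pre` per patient; the cohort median splits patients
#' into "Large" (delta below the median, i.e. stronger decrease) versus
#' "Small" (delta at or above the median) methylation decrease groups.
#' With an even number of patients the median is the mean of the two
#' central order statistics. The split value is recomputed per cohort.
#'
#' @param pre_scores,post_scores Named numeric vectors (names =
#'   patient ids); patients present in only one vector are excluded and
#'   reported.
#' @param deltas Optional named vector of per-patient deltas to stratify
#'   on instead of the raw `post - pre` difference (e.g. tumor-content
#'   adjusted deltas from [tf_adjusted_delta()]).
#' @return List: `deltas` (data frame patient_id, pre, post, delta,
#'   decrease_group), `median_delta`, `unpaired` (excluded ids),
#'   `degenerate` (all deltas equal).
#' @export
delta_stratify <- function(pre_scores, post_scores, deltas = NULL) {
  ids <- intersect(names(pre_scores), names(post_scores))
  unpaired <- union(setdiff(names(pre_scores), ids),
                    setdiff(names(post_scores), ids))
  if (length(ids) == 0) stop("no paired patients")
  delta <- if (is.null(deltas)) post_scores[ids] - pre_scores[ids]
           else deltas[ids]
  m <- stats::median(delta)
  grp <- ifelse(delta < m, "Large", "Small")
  list(deltas = data.frame(patient_id = ids,
                           pre = as.numeric(pre_scores[ids]),
                           post = as.numeric(post_scores[ids]),
                           delta = as.numeric(delta),
                           decrease_group = grp,
                           stringsAsFactors = FALSE),
       median_delta = m,
       unpaired = unpaired,
       degenerate = length(unique(delta)) == 1)
}
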