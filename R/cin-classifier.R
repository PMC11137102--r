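# CIN cluster classification: 102-dimensional peak features, the
# tumor-content scaling procedure, nearest-centroid assignment with a
# genome-altered-burden guard, and plasma-vs-tissue concordance statistics.

#' Extract peak features from a segmented profile
#'
#' One feature per peak region: the bin-length-weighted mean of the
#' overlapping segment log2 ratios. Peaks with no unmasked overlap get 0
#' and are flagged.
#'
#' @param seg A `segmented_cna_profile`.
#' @param peaks Peak region table with `bin_start`, `bin_end` (half-open
#'   global 0-based bin indices) and `label`.
#' @return List of class `"peak_feature_vector"`: `sample_id`, `features`
#'   (named numeric), `no_overlap` (logical flags), `scaled` (FALSE),
#'   `tumor_fraction` (NA until scaling).
#' @export
extract_peak_features <- function(seg, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) stop("empty peak set")
  # per-bin segment mean, NA where masked / unsegmented
  nb <- nrow(seg$bins)
  bin_lr <- rep(NA_real_, nb)
  s <- seg$segments
  for (i in seq_len(nrow(s)))
    bin_lr[(s$start_bin[i] + 1L):s$end_bin[i]] <- s$mean_lr[i]
  bin_lr[seg$mask] <- NA_real_
  feats <- numeric(nrow(peaks)); miss <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    v <- bin_lr[(peaks$bin_start[i] + 1L):peaks$bin_end[i]]
    if (all(is.na(v))) { feats[i] <- 0; miss[i] <- TRUE }
    else feats[i] <- mean(v, na.rm = TRUE)
  }
  names(feats) <- peaks$label
  structure(list(sample_id = seg$sample_id, features = feats,
                 no_overlap = miss, scaled = FALSE,
                 tumor_fraction = NA_real_),
            class = "peak_feature_vector")
}

#' Rescale log2 ratios to their tumor-equivalent values
#'
#' The observed copy number in a sample with tumor fraction `tf` is the
#' mixture `CN_obs = 2 (1 - tf) + tf CN_tumor`; low tumor content pulls
#' every ratio toward 0. This inverts the dilution in linear copy-number
#' space: `CN_obs = 2 * 2^L`, `L' = log2((2 + (CN_obs - 2) / tf) / 2)`,
#' with the copy-number argument clipped at `cn_min` so `L'` stays finite.
#' Tumor fractions below `floor_tf` are clipped to `floor_tf` to cap noise
#' amplification.
#'
#' @param x Numeric vector of log2 ratios, a `peak_feature_vector`, or a
#'   `segmented_cna_profile` (segment means are rescaled and the
#'   genome-altered fraction recomputed).
#' @param tf Tumor fraction in (0, 1].
#' @param floor_tf Lower clip for `tf`.
#' @param cn_min Positive clip for the rescaled copy number.
#' @return Object of the same type with rescaled log2 ratios; feature
#'   vectors and profiles record the `tf` used and `scaled = TRUE`.
#' @export
scale_profile_for_tumor_fraction <- function(x, tf, floor_tf = 0.03,
                                             cn_min = 0.1) {
  tf <- max(tf, floor_tf)
  if (!is.finite(tf) || tf <= 0) stop("tumor fraction must be positive")
  if (tf > 1) stop("tumor fraction must not exceed 1")
  rescale <- function(L) {
    cn_obs <- 2 * 2^L
    log2(pmax(2 + (cn_obs - 2) / tf, cn_min) / 2)
  }
  if (inherits(x, "peak_feature_vector")) {
    x$features <- rescale(x$features)
    x$scaled <- TRUE
    x$tumor_fraction <- tf
    return(x)
  }
  if (inherits(x, "segmented_cna_profile")) {
    x$segments$mean_lr <- rescale(x$segments$mean_lr)
    altered <- abs(x$segments$mean_lr) > x$calling_threshold
    x$genome_altered_fraction <-
      sum(x$segments$n_bins[altered]) / sum(x$segments$n_bins)
    x$scaled <- TRUE
    x$tumor_fraction <- tf
    return(x)
  }
  rescale(x)
}

#' Cohort-level plasma/tissue tumor-fraction scaling factor
#'
#' Mean over patients of `plasma tf / tissue tf`. Used in place of a
#' per-sample tumor fraction for cohorts without matched tissue.
#'
#' @param tissue_tfs,plasma_tfs Paired positive tissue and plasma tumor
#'   fractions.
#' @return Positive scalar.
#' @export
derive_cohort_scaling_factor <- function(tissue_tfs, plasma_tfs) {
  stopifnot(length(tissue_tfs) == length(plasma_tfs), length(tissue_tfs) > 0)
  if (any(tissue_tfs <= 0)) stop("tissue tumor fractions must be positive")
  mean(plasma_tfs / tissue_tfs)
}

#' Assign a CIN cluster by burden rule plus nearest centroid
#'
#' Profiles whose genome-altered fraction falls below `burden_threshold`
#' are assigned cluster 1 (low CIN) outright. Otherwise the sample goes to
#' the centroid with the highest Pearson correlation, ties broken toward
#' the lower cluster index. A zero-variance feature vector cannot be
#' correlated and falls back to cluster 1 with a warning flag.
#'
#' @param fv A `peak_feature_vector` (scaled or not).
#' @param centroids 3 x n_peaks matrix (rows = clusters 1..3).
#' @param burden Genome-altered fraction of the profile.
#' @param burden_threshold Below this, cluster 1 is forced.
#' @return List of class `"cluster_assignment"`: `sample_id`, `cluster`,
#'   `cin_high`, `similarity` (correlation with each centroid),
#'   `burden`, `forced_by_burden`, `degenerate`.
#' @export
assign_cluster <- function(fv, centroids, burden, burden_threshold = 0.05) {
  stopifnot(length(fv$features) == ncol(centroids))
  sim <- rep(NA_real_, 3)
  degenerate <- stats::sd(fv$features) == 0
  if (!degenerate)
    sim <- vapply(1:3, function(k) {
      if (stats::sd(centroids[k, ]) == 0) return(NA_real_)
      stats::cor(fv$features, centroids[k, ])
    }, numeric(1))
  if (burden < burden_threshold) {
    cl <- 1L; forced <- TRUE
  } else if (degenerate || all(is.na(sim))) {
    warning("zero-variance feature vector; falling back to cluster 1")
    cl <- 1L; forced <- FALSE
  } else {
    cl <- which.max(replace(sim, is.na(sim), -Inf))  # ties -> lowest index
    forced <- FALSE
  }
  structure(list(sample_id = fv$sample_id, cluster = as.integer(cl),
                 cin_high = cl %in% c(2L, 3L), similarity = sim,
                 burden = burden, forced_by_burden = forced,
                 degenerate = degenerate),
            class = "cluster_assignment")
}

#' Plasma-vs-tissue cluster concordance
#'
#' Pairs plasma and tissue assignments by `patient_id` and tabulates the
#' 3x3 confusion matrix (rows = plasma cluster P1..P3, columns = tissue
#' cluster T1..T3), the exact match rate (trace / n), and the binary
#' CIN-high/CIN-low accuracy — the fraction of pairs where plasma and
#' tissue agree on cluster membership in \{2, 3\} versus \{1\}.
#'
#' @param plasma,tissue Data frames with columns `patient_id` and
#'   `cluster` (or lists of `cluster_assignment`s paired by position with
#'   `patient_id`s attached via `sample_id`).
#' @return List of class `"cin_concordance"`: `confusion` (3x3 matrix),
#'   `n`, `match_rate`, `binary_accuracy`.
#' @export
concordance <- function(plasma, tissue) {
  plasma <- .as_assignment_df(plasma); tissue <- .as_assignment_df(tissue)
  un_p <- setdiff(plasma$patient_id, tissue$patient_id)
  un_t <- setdiff(tissue$patient_id, plasma$patient_id)
  if (length(un_p) > 0 || length(un_t) > 0)
    stop("unpaired patient ids: ", paste(c(un_p, un_t), collapse = ", "))
  m <- merge(plasma, tissue, by = "patient_id", suffixes = c("_plasma", "_tissue"))
  conf <- table(factor(m$cluster_plasma, levels = 1:3),
                factor(m$cluster_tissue, levels = 1:3))
  conf <- matrix(as.integer(conf), 3, 3,
                 dimnames = list(paste0("P", 1:3), paste0("T", 1:3)))
  n <- sum(conf)
  hi_p <- m$cluster_plasma %in% c(2, 3); hi_t <- m$cluster_tissue %in% c(2, 3)
  structure(list(confusion = conf, n = n,
                 match_rate = sum(diag(conf)) / n,
                 binary_accuracy = mean(hi_p == hi_t)),
            class = "cin_concordance")
}

.as_assignment_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("patient_id", "cluster") %in% names(x)))
    return(x[, c("patient_id", "cluster")])
  }
  data.frame(patient_id = vapply(x, `[[`, "", "sample_id"),
             cluster = vapply(x, `[[`, integer(1), "cluster"))
}

#' Rebuild paired cluster labels from 3x3 confusion counts
#'
#' Expands a printed confusion table (plasma cluster x tissue cluster
#' counts) into per-patient paired labels, so the published counts can be
#' pushed through [concordance()] like any other cohort.
#'
#' @param counts 3x3 matrix of counts, rows = plasma P1..P3, columns =
#'   tissue T1..T3.
#' @return List with `plasma` and `tissue` data frames for [concordance()].
#' @export
pairs_from_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  p <- rep(rep(1:3, 3), as.vector(counts))
  t <- rep(rep(1:3, each = 3), as.vector(counts))
  ids <- sprintf("P%03d", seq_along(p))
  list(plasma = data.frame(patient_id = ids, cluster = p),
       tissue = data.frame(patient_id = ids, cluster = t))
}

#' Sample-by-sample Spearman correlation matrix of peak features
#'
#' Rows/columns are ordered with each patient's tissue sample immediately
#' followed by its plasma sample, so matched pairs sit adjacent to the
#' diagonal. Samples with constant feature vectors get `NA` correlations.
#'
#' @param features List of `peak_feature_vector`s, in the desired
#'   alternating tissue/plasma order.
#' @return Symmetric matrix with unit diagonal.
#' @export
peak_correlation_matrix <- function(features) {
  if (length(features) < 2) stop("need at least 2 samples")
  M <- vapply(features, `[[`, numeric(length(features[[1]]$features)),
              "features")
  ids <- vapply(features, `[[`, "", "sample_id")
  const <- apply(M, 2, function(v) stats::sd(v) == 0)
  R <- suppressWarnings(stats::cor(M, method = "spearman"))
  R[const, ] <- NA_real_; R[, const] <- NA_real_
  diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  R
}
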