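# Peak features, tumor-content scaling, cluster assignment, concordance.

test_that("peak features are length-weighted means of overlapping segments", {
  peaks <- data.frame(label = c("p1", "p2"), bin_start = c(10L, 50L),
                      bin_end = c(20L, 60L))
  zero <- manual_segments(list(list(level = 0, n = 100)))
  expect_equal(unname(extract_peak_features(zero, peaks)$features), c(0, 0))
  # one segment at log2 = 1 exactly covering peak 1
  seg <- manual_segments(list(list(level = 0, n = 10),
                              list(level = 1, n = 10),
                              list(level = 0, n = 80)))
  fv <- extract_peak_features(seg, peaks)
  expect_equal(unname(fv$features), c(1, 0))
  # peak half covered by a log2 = 1 segment, half by 0: mean 0.5
  seg_half <- manual_segments(list(list(level = 0, n = 15),
                                   list(level = 1, n = 40),
                                   list(level = 0, n = 45)))
  expect_equal(unname(extract_peak_features(seg_half, peaks)$features[1]), 0.5)
  expect_error(extract_peak_features(zero, peaks[0, ]), "empty peak set")
})

test_that("masked peaks are imputed as zero and flagged", {
  peaks <- data.frame(label = "p1", bin_start = 10L, bin_end = 20L)
  seg <- manual_segments(list(list(level = 0.7, n = 100)))
  seg$mask[11:20] <- TRUE
  fv <- extract_peak_features(seg, peaks)
  expect_equal(unname(fv$features), 0)
  expect_true(fv$no_overlap)
})

test_that("tumor-content scaling inverts the dilution exactly", {
  # undiluted sample: identity
  L <- c(-0.6, -0.1, 0, 0.2, 0.9)
  expect_equal(scale_profile_for_tumor_fraction(L, 1), L)
  # neutral ratios are invariant at any tumor fraction
  expect_equal(scale_profile_for_tumor_fraction(0, 0.2), 0)
  # hand-computed inversion: L = 0.1 at tf = 0.25
  # CN_obs = 2 * 2^0.1 = 2.14355; L' = log2((2 + 0.14355 / 0.25) / 2)
  expect_equal(scale_profile_for_tumor_fraction(0.1, 0.25),
               log2((2 + (2 * 2^0.1 - 2) / 0.25) / 2))
  expect_equal(scale_profile_for_tumor_fraction(0.1, 0.25), 0.364,
               tolerance = 1e-3)
  expect_error(scale_profile_for_tumor_fraction(L, -1, floor_tf = 0),
               "positive")
})

test_that("scaling then re-diluting is the identity and preserves signs", {
  dilute <- function(L, tf) log2((2 + (2 * 2^L - 2) * tf) / 2)
  set.seed(301)
  for (tf in c(0.1, 0.3, 0.7)) {
    # stay off the clipping floor: scaled CN must remain >= cn_min
    L_min <- log2(pmax(1 + (0.1 - 2) * tf / 2, 0.01)) + 0.01
    L <- runif(50, L_min, 0.8)
    round_trip <- dilute(scale_profile_for_tumor_fraction(L, tf), tf)
    expect_equal(round_trip, L, tolerance = 1e-12)
    expect_equal(sign(scale_profile_for_tumor_fraction(L, tf)), sign(L))
  }
})

test_that("scaling a segmented profile rescales means and burden", {
  tf <- 0.1
  seg <- manual_segments(list(
    list(level = 0, n = 80),
    list(level = log2((2 * (1 - tf) + 3 * tf) / 2), n = 20)))  # 0.0704
  expect_equal(seg$genome_altered_fraction, 0)  # diluted gain below 0.1
  seg_s <- scale_profile_for_tumor_fraction(seg, tf)
  expect_equal(seg_s$segments$mean_lr[2], log2(3 / 2), tolerance = 1e-12)
  expect_equal(seg_s$genome_altered_fraction, 0.2)
})

test_that("cohort scaling factor is the mean plasma/tissue ratio", {
  expect_equal(derive_cohort_scaling_factor(c(0.2, 0.4), c(0.1, 0.2)), 0.5)
  expect_equal(derive_cohort_scaling_factor(c(0.3, 0.1), c(0.3, 0.1)), 1)
  expect_error(derive_cohort_scaling_factor(c(0.2, 0), c(0.1, 0.1)),
               "positive")
  # recovery of the generator's plasma:tissue ratio
  cohort <- simulate_cohort(cohort_config(n_patients = 50, seed = 302),
                            components = character(0))
  expect_equal(derive_cohort_scaling_factor(cohort$truth$tf_tissue,
                                            cohort$truth$tf_plasma),
               0.6, tolerance = 1e-12)
})

test_that("cluster assignment follows the burden rule then correlation", {
  centroids <- fix_arch$centroids
  mk_fv <- function(v) structure(
    list(sample_id = "s", features = v, no_overlap = rep(FALSE, length(v)),
         scaled = TRUE, tumor_fraction = 1), class = "peak_feature_vector")
  # a sample equal to centroid 2 with high burden: cluster 2, CIN-high
  a2 <- assign_cluster(mk_fv(centroids[2, ]), centroids, burden = 0.3)
  expect_identical(a2$cluster, 2L)
  expect_true(a2$cin_high)
  expect_equal(a2$similarity[2], 1)
  # flat zero vector: burden 0 forces cluster 1
  a1 <- assign_cluster(mk_fv(rep(0, ncol(centroids))), centroids, burden = 0)
  expect_identical(a1$cluster, 1L)
  expect_false(a1$cin_high)
  expect_true(a1$forced_by_burden)
  # zero-variance features with burden above threshold: warned fallback
  expect_warning(
    a0 <- assign_cluster(mk_fv(rep(0.5, ncol(centroids))), centroids,
                         burden = 0.3),
    "zero-variance")
  expect_identical(a0$cluster, 1L)
})

test_that("concordance reproduces arithmetic on published-style confusion
           counts", {
  # identity confusion: everything matches
  ident <- pairs_from_confusion(diag(c(10, 20, 22)))
  ci <- concordance(ident$plasma, ident$tissue)
  expect_equal(ci$match_rate, 1)
  expect_equal(ci$binary_accuracy, 1)
  # mixed counts, checked by hand: 3+15+19 = 37 of 52 match;
  # high/low errors only from P1-T2 (4)
  counts <- matrix(0, 3, 3)
  counts[1, 1] <- 3; counts[2, 2] <- 15; counts[3, 3] <- 19
  counts[1, 2] <- 4; counts[2, 3] <- 6; counts[3, 2] <- 5
  pp <- pairs_from_confusion(counts)
  cc <- concordance(pp$plasma, pp$tissue)
  expect_equal(cc$n, 52)
  expect_equal(cc$match_rate, 37 / 52)
  expect_equal(cc$binary_accuracy, 48 / 52)
  expect_equal(unname(cc$confusion["P2", "T3"]), 6L)
  # unpaired ids are an error naming the offenders
  bad <- pp$plasma; bad$patient_id[1] <- "ZZZ"
  expect_error(concordance(bad, pp$tissue), "ZZZ")
})

test_that("matched tissue/plasma pairs correlate above unmatched pairs", {
  set.seed(303)
  centroids <- fix_arch$centroids
  fvs <- list()
  cl <- rep(1:3, each = 4)
  for (i in seq_along(cl)) {
    base <- centroids[cl[i], ]
    for (kind in c("tissue", "plasma")) {
      v <- base + rnorm(length(base), 0, 0.15)
      fvs[[length(fvs) + 1]] <- structure(
        list(sample_id = sprintf("P%02d_%s", i, kind), features = v,
             no_overlap = rep(FALSE, length(v)), scaled = TRUE,
             tumor_fraction = 1), class = "peak_feature_vector")
    }
  }
  R <- peak_correlation_matrix(fvs)
  expect_equal(unname(diag(R)), rep(1, length(fvs)))
  expect_equal(R, t(R))
  n <- length(fvs)
  matched <- R[cbind(seq(1, n, 2), seq(2, n, 2))]
  off <- R[upper.tri(R)]
  unmatched <- setdiff(off, matched)
  expect_gt(mean(matched), mean(unmatched))
  # identical and anti-ranked vectors
  v <- seq_len(10)
  mk <- function(id, x) structure(
    list(sample_id = id, features = x, no_overlap = rep(FALSE, 10),
         scaled = FALSE, tumor_fraction = NA_real_),
    class = "peak_feature_vector")
  R2 <- peak_correlation_matrix(list(mk("a", v), mk("b", v), mk("c", rev(v))))
  expect_equal(unname(R2["a", "b"]), 1)
  expect_equal(unname(R2["a", "c"]), -1)
  # constant vector: correlations reported missing
  R3 <- peak_correlation_matrix(list(mk("a", v), mk("k", rep(1, 10))))
  expect_true(is.na(R3["a", "k"]))
  expect_equal(unname(R3["k", "k"]), 1)
})

test_that("simulated tissue at high tumor fraction recovers cluster labels", {
  set.seed(304)
  ok <- 0; total <- 0
  for (k in 1:3) for (r in 1:4) {
    tf <- runif(1, 0.3, 0.5)
    p <- simulate_binned_reads(fix_arch$templates[k, ], tf,
                               fix_cfg$reads_per_sample, fix_arch$bins,
                               nb_size = fix_cfg$nb_size)
    seg <- segment_profile(normalize_profile(p, fix_panel))
    est <- estimate_tumor_fraction(seg)
    a <- classify_cin_sample(seg, est$tf, fix_arch$peaks, fix_arch$centroids)
    total <- total + 1; ok <- ok + (a$cluster == k)
  }
  expect_gte(ok / total, 0.95)
})
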