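# Region betas, QC, tumor-content deconvolution, score model, delta
# stratification.

test_that("region betas pool counts and flag zero coverage", {
  counts <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2"),
    region_id = c("r1", "r2", "r2", "r1", "r2"),
    meth = c(8, 3, 1, 0, 0),
    unmeth = c(2, 1, 3, 5, 0))
  mm <- region_betas(counts)
  expect_equal(mm$beta["s1", "r1"], 0.8)
  # CpG-level rows pooled: (3 + 1) / (3 + 1 + 1 + 3) = 0.5
  expect_equal(mm$beta["s1", "r2"], 0.5)
  expect_equal(mm$beta["s2", "r1"], 0)
  expect_true(is.na(mm$beta["s2", "r2"]))
  expect_equal(mm$coverage["s1", "r2"], 8)
  counts$meth[1] <- -1
  expect_error(region_betas(counts), "non-negative")
})

test_that("QC retains samples passing both conversion and coverage gates", {
  rec <- data.frame(sample_id = c("a", "b", "c"),
                    bisulfite_conversion_rate = c(0.94, 0.99, 0.96),
                    mean_region_coverage = c(30, 9.5, 10))
  q <- qc_filter(rec)
  expect_identical(q$retained, "c")
  expect_identical(q$records$fail_reason, c("conversion", "coverage", NA))
  # a cohort of 122 with 1 conversion failure and 22 coverage failures
  # retains exactly 99
  big <- data.frame(
    sample_id = sprintf("s%03d", 1:122),
    bisulfite_conversion_rate = c(0.93, rep(0.99, 121)),
    mean_region_coverage = c(30, rep(5, 22), rep(25, 99)))
  qb <- qc_filter(big)
  expect_identical(qb$n_retained, 99L)
  expect_identical(qb$n_excluded, 23L)
  expect_equal(unname(qb$exclusions["conversion"]), 1)
  expect_equal(unname(qb$exclusions["coverage"]), 22)
})

test_that("tumor-content deconvolution inverts the mixture", {
  # pure tumor: identity
  expect_equal(normalize_for_tumor_content(0.37, 0.02, 1), 0.37)
  # observed equal to the healthy reference: fixed point at any tf
  expect_equal(normalize_for_tumor_content(0.02, 0.02, 0.4), 0.02)
  # hand inversion: (0.5 - 0.4 * 0.02) / 0.6 = 0.82
  expect_equal(normalize_for_tumor_content(0.5, 0.02, 0.6), 0.492 / 0.6)
  expect_error(normalize_for_tumor_content(0.5, 0.02, NA), "positive")
  # exact inverse of the noiseless simulator for tf above the floor
  sim <- simulate_methylation(tf_pre = c(0.05, 0.2, 0.6),
                              tf_post = c(0.05, 0.2, 0.6),
                              responder = c(FALSE, FALSE, FALSE),
                              n_regions = 60, noise_sd = 0, seed = 501)
  recovered <- normalize_for_tumor_content(sim$pre, sim$region_base,
                                           tf = c(0.05, 0.2, 0.6))
  expect_equal(recovered, sim$tumor_pre, tolerance = 1e-12)
})

test_that("renormalization re-expresses betas at a target tumor content", {
  sim <- simulate_methylation(tf_pre = c(0.3, 0.5), tf_post = c(0.3, 0.5),
                              responder = c(FALSE, FALSE),
                              n_regions = 40, noise_sd = 0, seed = 502)
  # noiseless: remixing at tf 0.1 equals the direct mixture at tf 0.1
  adj <- renormalize_tumor_content(sim$pre, sim$region_base,
                                   tf = c(0.3, 0.5), tf_target = 0.1)
  direct <- 0.9 * matrix(sim$region_base, 2, 40, byrow = TRUE) +
    0.1 * sim$tumor_pre
  expect_equal(adj, direct, tolerance = 1e-12)
})

test_that("noiseless simulator obeys the closed-form mixture", {
  # 0.6 * 0.02 + 0.4 * 0.7 = 0.292
  expect_equal((1 - 0.4) * 0.02 + 0.4 * 0.7, 0.292)
  sim <- simulate_methylation(tf_pre = 0.4, tf_post = 0.4, responder = FALSE,
                              n_regions = 30, noise_sd = 0, seed = 503)
  expect_equal(as.numeric(sim$pre),
               0.6 * sim$region_base + 0.4 * as.numeric(sim$tumor_pre),
               tolerance = 1e-12)
  # healthy rows are the baseline itself when noiseless
  expect_equal(as.numeric(sim$healthy[1, ]), sim$region_base)
  expect_error(simulate_methylation(1.5, 0.5, TRUE), "\\[0, 1\\]")
})

test_that("score model separates constructed classes and is reproducible", {
  set.seed(504)
  n_r <- 60
  healthy <- matrix(pmin(1, pmax(0, rnorm(40 * n_r, 0.02, 0.01))), 40, n_r)
  tumor <- matrix(pmin(1, pmax(0, rnorm(40 * n_r, 0.6, 0.05))), 40, n_r)
  colnames(healthy) <- colnames(tumor) <- sprintf("r%02d", 1:n_r)
  model <- train_score_model(tumor, healthy, seed = 7)
  # perfectly separated classes: held-out (OOB) AUC = 1
  labels <- c(rep(1, 40), rep(0, 40))
  expect_equal(roc_auc(model$oob_scores, labels), 1)
  # scoring the archetypes lands on the right side
  expect_lt(methylation_score(model, colMeans(healthy)), 0.5)
  expect_gt(methylation_score(model, colMeans(tumor)), 0.5)
  # determinism under the seed
  model2 <- train_score_model(tumor, healthy, seed = 7)
  expect_identical(model$oob_scores, model2$oob_scores)
  expect_error(train_score_model(tumor[1:3, ], healthy, seed = 1),
               "at least 5")
})

test_that("randomly relabelled training data scores near chance", {
  set.seed(505)
  n_r <- 50
  X <- matrix(runif(80 * n_r, 0, 0.1), 80, n_r)
  colnames(X) <- sprintf("r%02d", 1:n_r)
  # the two "classes" are draws from the same distribution
  model <- train_score_model(X[1:40, ], X[41:80, ], seed = 9)
  auc <- roc_auc(model$oob_scores, c(rep(1, 40), rep(0, 40)))
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("scores are probabilities and missing regions are handled", {
  set.seed(506)
  n_r <- 40
  healthy <- matrix(runif(20 * n_r, 0, 0.05), 20, n_r)
  tumor <- matrix(runif(20 * n_r, 0.3, 0.9), 20, n_r)
  colnames(healthy) <- colnames(tumor) <- sprintf("r%02d", 1:n_r)
  model <- train_score_model(tumor, healthy, seed = 3)
  probe <- matrix(runif(10 * n_r), 10, n_r,
                  dimnames = list(NULL, colnames(healthy)))
  s <- methylation_score(model, probe)
  expect_true(all(s >= 0 & s <= 1))
  # a few missing regions are imputed from the healthy reference
  partial <- probe[1, 1:30]
  s1 <- methylation_score(model, partial)
  expect_equal(attr(s1, "n_imputed"), 10)
  expect_true(s1 >= 0 && s1 <= 1)
  # more than half missing is refused
  expect_error(methylation_score(model, probe[1, 1:10]), "50%")
})

test_that("delta stratification splits at the recomputed cohort median", {
  pre <- c(a = 0.5, b = 0.6, c = 0.4, d = 0.3)
  post <- pre + c(-0.10, -0.06, -0.02, 0.01)
  s <- delta_stratify(pre, post)
  # order statistics by hand: median of {-0.10,-0.06,-0.02,0.01} = -0.04
  expect_equal(s$median_delta, -0.04)
  expect_identical(s$deltas$decrease_group, c("Large", "Large", "Small", "Small"))
  expect_false(s$degenerate)
  # ties: all equal deltas all land in "Small" (delta >= median), flagged
  pre_dyadic <- c(a = 0.5, b = 0.25, c = 0.75, d = 0.375)
  s_eq <- delta_stratify(pre_dyadic, pre_dyadic - 0.125)
  expect_true(all(s_eq$deltas$decrease_group == "Small"))
  expect_true(s_eq$degenerate)
  # a cohort whose median lands at -0.037: below is Large, above is Small
  pre3 <- c(x = 0.5, y = 0.5, z = 0.5)
  post3 <- pre3 + c(-0.10, -0.037, 0)
  s3 <- delta_stratify(pre3, post3)
  expect_equal(s3$median_delta, -0.037)
  expect_identical(s3$deltas$decrease_group, c("Large", "Small", "Small"))
  # unpaired patients are excluded and reported
  s_un <- delta_stratify(c(pre, e = 0.7), post)
  expect_identical(s_un$unpaired, "e")
  expect_identical(nrow(s_un$deltas), 4L)
})

test_that("tf adjustment removes the constructed tumor-content dependence", {
  set.seed(507)
  n <- 120
  tf_pre <- runif(n, 0.05, 0.3)
  tf_post <- tf_pre * runif(n, 0.4, 1.05)
  true_effect <- rnorm(n, -0.05, 0.03)
  raw_delta <- true_effect + 1.5 * (tf_post - tf_pre) + rnorm(n, 0, 0.01)
  post <- 0.5 + raw_delta; pre <- rep(0.5, n)
  names(post) <- names(pre) <- sprintf("P%03d", 1:n)
  adj <- tf_adjusted_delta(pre, post, tf_pre, tf_post)
  expect_lt(abs(cor(adj$delta, tf_post - tf_pre)), 0.05)
  expect_gt(cor(adj$delta, true_effect), 0.9)
  # the overall level of the deltas is preserved
  expect_equal(mean(adj$delta), mean(adj$raw_delta), tolerance = 1e-12)
})
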