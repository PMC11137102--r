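# Survival, rank and classification statistics against enumeration and
# hand-computed oracles.

test_that("binomial sample-size calculation matches closed form and is
           self-consistent", {
  expect_identical(min_samples_binomial(0.1, 0.95), 29L)
  expect_equal(round(100 * confidence_at_n(0.1, 24)), 92)
  expect_identical(min_samples_binomial(1.0, 0.9), 1L)
  # direct enumeration: 1 - 0.5^4 = 0.9375 < 0.95 <= 1 - 0.5^5
  expect_identical(min_samples_binomial(0.5, 0.95), 5L)
  expect_identical(confidence_at_n(0.2, 0), 0)
  expect_error(min_samples_binomial(0, 0.95), "unreachable")
  # mutual consistency over a parameter sweep
  for (p in c(0.05, 0.1, 0.3, 0.7)) for (conf in c(0.8, 0.9, 0.95, 0.99)) {
    n <- min_samples_binomial(p, conf)
    expect_gte(confidence_at_n(p, n), conf)
    expect_lt(confidence_at_n(p, n - 1), conf)
  }
})

test_that("Mann-Whitney exact path agrees with full enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2 * (1/20) over all 20 rank assignments
  expect_identical(r$method, "exact")
  # property sweep vs wilcox.test's exact distribution, all n_a, n_b <= 5
  set.seed(11)
  for (na in 2:5) for (nb in 2:5) {
    x <- sample(seq_len(50), na); y <- sample(setdiff(seq_len(50), x), nb)
    mine <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation handles ties and symmetry", {
  a <- c(1, 2, 2, 3, 5, 5, 8, 9, 9, 9)
  b <- c(2, 3, 3, 4, 5, 7, 7, 9, 10, 11)
  mine <- mann_whitney(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_identical(mine$method, "normal")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # symmetry
  expect_equal(mann_whitney(b, a)$p, mine$p, tolerance = 1e-12)
  # identical samples: approximation path, p = 1
  same <- rep(c(1, 2, 3, 4, 5), 2)
  expect_equal(mann_whitney(same, same)$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Spearman correlation matches hand-ranked example and cor.test", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(1:10, (1:10)^3)$p, 0)
  # hand computation: ranks (1,2,3,4) vs (2,1,4,3), d^2 = 4, rho = 1 - 24/60
  r <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  mine <- spearman_cor(x, y)
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
})

test_that("ROC AUC counts pairwise wins with ties at one half", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # 4 pairs, positive wins 3: (0.35>0.1), (0.35<0.4), (0.8>both)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  # complement identity without ties
  set.seed(31)
  s <- rnorm(40); l <- rep(c(0, 1), 20)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Kaplan-Meier estimator matches hand-computed product limits", {
  km <- kaplan_meier(1:5, rep(1, 5))
  expect_equal(km$all$steps$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$all$median, 3)
  # all censored: no steps, median undefined
  km0 <- kaplan_meier(c(3, 8, 12), c(0, 0, 0))
  expect_true(is.na(km0$all$median))
  expect_identical(nrow(km0$all$steps), 0L)
  # mixed 6-record hand oracle:
  # t=1 (risk 6, d 1) S=5/6; t=2 (risk 5, d 1) S=2/3; t=3 (risk 3, d 1)
  # S=4/9; t=5 (risk 1, d 1) S=0
  km6 <- kaplan_meier(c(1, 2, 2, 3, 4, 5), c(1, 0, 1, 1, 0, 1))
  expect_equal(km6$all$steps$surv, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_equal(km6$all$median, 3)
  # survival curve is non-increasing and starts below 1
  expect_true(all(diff(km6$all$steps$surv) <= 0))
  expect_lte(km6$all$steps$surv[1], 1)
})

test_that("Kaplan-Meier agrees with the survival package", {
  set.seed(41)
  tt <- rexp(60, 1 / 100); ee <- rbinom(60, 1, 0.7)
  km <- kaplan_meier(tt, ee)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  ref <- summary(sf, times = km$all$steps$time)
  expect_equal(km$all$steps$surv, ref$surv, tolerance = 1e-12)
})

test_that("Cox partial likelihood maximum matches a brute-force grid", {
  # 4 records, binary covariate, no ties
  tt <- c(2, 5, 7, 11); ee <- c(1, 1, 0, 1); x <- c(1, 0, 1, 0)
  loglik <- function(b) {
    # independent direct Breslow computation
    ll <- 0
    for (i in which(ee == 1)) {
      risk <- which(tt >= tt[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  fit <- cox_fit(tt, ee, cbind(grp = x))
  expect_equal(unname(fit$coef), b_star, tolerance = 1e-4)
})

test_that("Cox fit reproduces survival::coxph with Breslow ties", {
  set.seed(51)
  n <- 80
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  tt <- round(rexp(n, exp(-0.7 * x1 + 0.3 * x2) / 50)) + 1
  ee <- rbinom(n, 1, 0.8)
  fit <- cox_fit(tt, ee, cbind(x1 = x1, x2 = x2))
  ref <- survival::coxph(survival::Surv(tt, ee) ~ x1 + x2, ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_true(all(fit$ci_lower <= fit$hr & fit$hr <= fit$ci_upper))
})

test_that("Cox fit reports degenerate inputs instead of silent results", {
  expect_error(cox_fit(1:6, rep(1, 6), cbind(x = rep(1, 6))), "constant")
  # perfectly separating covariate: monotone likelihood
  tt <- c(1, 2, 3, 10, 11, 12); ee <- rep(1, 6); x <- c(1, 1, 1, 0, 0, 0)
  expect_error(cox_fit(tt, ee, cbind(x = x)), "monotone|identifiable")
})

test_that("multivariate Cox wrapper encodes groups and covariates", {
  set.seed(61)
  n <- 120
  rec <- data.frame(
    time = rexp(n, 1 / 300) + 1, event = rbinom(n, 1, 0.8),
    cluster = sample(1:3, n, replace = TRUE),
    age = round(runif(n, 45, 80)),
    gender = sample(c("M", "F"), n, TRUE),
    tnm_stage = sample(c("III", "IV"), n, TRUE))
  fit <- cox_multivariate(rec, "cluster", ref = "1")
  expect_setequal(names(fit$hr)[1:2], c("cluster2", "cluster3"))
  expect_true("age_gt65" %in% names(fit$hr))
  ref <- survival::coxph(
    survival::Surv(time, event) ~ factor(cluster) + I(age > 65) +
      factor(gender) + factor(tnm_stage), data = rec, ties = "breslow")
  expect_equal(unname(fit$coef["cluster2"]),
               unname(coef(ref)["factor(cluster)2"]), tolerance = 1e-6)
})

test_that("logistic combination is honest about an uninformative feature", {
  set.seed(71)
  n <- 80
  lab <- rep(c(0, 1), each = n / 2)
  good <- lab + rnorm(n, 0, 0.8)
  noise <- rnorm(n)
  comb <- combine_scores_logistic(good, noise, lab, seed = 5)
  expect_lt(abs(comb$auc_combined - comb$auc_a), 0.08)
  # a perfectly separating feature dominates
  sep <- combine_scores_logistic(lab, noise, lab, seed = 5)
  expect_equal(sep$auc_combined, 1)
  expect_true(sep$ridge_used)
  # determinism
  again <- combine_scores_logistic(good, noise, lab, seed = 5)
  expect_identical(comb$prob, again$prob)
})

test_that("significance stars follow the boxplot convention", {
  expect_identical(signif_stars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
                   c("ns", "*", "**", "***", "****"))
})
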