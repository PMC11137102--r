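# Two-sample, correlation and classification statistics used across the
# pipeline. These are implemented directly (with exact small-sample paths)
# so the test suite can hold them against enumeration oracles.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic counts, over all
#' pairs, how often a value from `a` exceeds one from `b` (ties count 1/2).
#' For `min(n_a, n_b) <= 8` without ties the two-sided p-value is exact,
#' obtained by enumerating the null distribution of U; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return List with `U` (for sample `a`), `p` (two-sided), and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (min(n1, n2) <= 8 && !has_ties) {
    # exact null: every assignment of ranks to sample a is equally likely
    u_null <- .u_null_distribution(n1, n2)
    p <- 2 * min(sum(u_null <= U + 1e-9), sum(u_null >= U - 1e-9)) /
      length(u_null)
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

# all attainable U values for sample sizes n1, n2 (one entry per subset of
# ranks); feasible because it is only taken when min(n1, n2) <= 8
.u_null_distribution <- function(n1, n2) {
  ranks <- seq_len(n1 + n2)
  idx <- utils::combn(n1 + n2, n1)
  colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are assigned to ties. The two-sided p-value uses the
#' t-distribution with `n - 2` degrees of freedom; `|rho| = 1` gives p = 0.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, neither constant.
#' @return List with `rho`, `p` and `n`. Constant input yields `rho = NA`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1, logical, or a 2-level factor whose
#'   second level is taken as positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels must be paired")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels factor must have exactly 2 levels")
    labels <- as.integer(labels) - 1L
  }
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (anyNA(labels)) stop("labels must be binary")
  labels
}

#' Combine two scores with logistic regression, evaluated by leave-one-out
#'
#' Fits `label ~ score_a + score_b` by maximum likelihood; each sample's
#' combined probability is predicted from a model fitted without it
#' (leave-one-out), so the combined AUC is honestly cross-validated. When a
#' fit separates perfectly (diverging coefficients) it is refitted with a
#' small ridge penalty and flagged.
#'
#' @param score_a,score_b Numeric feature vectors.
#' @param labels Binary labels (see [roc_auc()]).
#' @param seed Integer seed; the procedure is deterministic but the seed is
#'   fixed anyway so callers can rely on bit-identical output.
#' @param ridge Penalty used on fallback, on standardized features.
#' @return List: `prob` (LOO combined probabilities), `auc_combined`,
#'   `auc_a`, `auc_b` (single-score AUCs), `ridge_used` flag.
#' @export
combine_scores_logistic <- function(score_a, score_b, labels, seed = 1L,
                                    ridge = 1e-3) {
  labels <- .as_binary_labels(labels)
  n <- length(labels)
  if (n < 10) stop("need at least 10 samples for leave-one-out evaluation")
  stopifnot(length(score_a) == n, length(score_b) == n)
  set.seed(as.integer(seed))
  X <- cbind(score_a, score_b)
  ridge_used <- FALSE
  prob <- numeric(n)
  for (i in seq_len(n)) {
    fit <- .logistic_irls(X[-i, , drop = FALSE], labels[-i], ridge = 0)
    if (!fit$converged || max(abs(fit$beta[-1])) > 25) {
      fit <- .logistic_irls(X[-i, , drop = FALSE], labels[-i], ridge = ridge)
      ridge_used <- TRUE
    }
    eta <- fit$beta[1] + sum(X[i, ] * fit$beta[-1])
    prob[i] <- stats::plogis(eta)
  }
  list(prob = prob,
       auc_combined = roc_auc(prob, labels),
       auc_a = roc_auc(score_a, labels),
       auc_b = roc_auc(score_b, labels),
       ridge_used = ridge_used)
}

# IRLS for logistic regression with optional ridge penalty on slopes
# (intercept unpenalized); features are standardized internally.
.logistic_irls <- function(X, y, ridge = 0, max_iter = 50, tol = 1e-10) {
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  p <- ncol(Z)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z, Z * w) + pen
    g <- crossprod(Z, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 1e3) break
  }
  # map back to the original feature scale
  b_slopes <- beta[-1] / scl
  b0 <- beta[1] - sum(b_slopes * ctr)
  list(beta = c(b0, b_slopes), converged = converged)
}
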