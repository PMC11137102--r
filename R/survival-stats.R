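# Survival machinery: product-limit estimator and Cox partial-likelihood
# fitting with Breslow tie handling. Implemented directly so the test suite
# can compare against brute-force likelihood grids and hand calculations.

#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive follow-up times (days).
#' @param event Binary event indicator (1 = event, 0 = censored).
#' @param group Optional grouping vector; one curve per group.
#' @return A list of class `"km_fit"`: per group a data.frame with columns
#'   `time`, `n_risk`, `n_event`, `surv` (one row per distinct event time),
#'   and `median` — the earliest time at which the survival function drops
#'   to 0.5 or below, `NA` if never reached. Empty groups are skipped with
#'   a warning.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  out <- list()
  for (g in unique(as.character(group))) {
    sel <- as.character(group) == g
    if (!any(sel)) { warning("empty group skipped: ", g); next }
    tt <- time[sel]; ee <- event[sel]
    ut <- sort(unique(tt[ee == 1]))
    if (length(ut) == 0) {
      out[[g]] <- list(steps = data.frame(time = numeric(0), n_risk = integer(0),
                                          n_event = integer(0), surv = numeric(0)),
                       median = NA_real_, n = sum(sel), n_events = 0L)
      next
    }
    n_risk <- vapply(ut, function(t) sum(tt >= t), numeric(1))
    n_event <- vapply(ut, function(t) sum(tt == t & ee == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
    out[[g]] <- list(steps = data.frame(time = ut, n_risk = n_risk,
                                        n_event = n_event, surv = surv),
                     median = med, n = sum(sel), n_events = sum(ee))
  }
  structure(out, class = "km_fit")
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step
#' halving. Ties are handled with the Breslow approximation: every event at
#' a tied time contributes the full risk-set denominator. Wald confidence
#' intervals and p-values are reported per term.
#'
#' @param time,event Follow-up times (> 0) and binary event indicators.
#' @param X Numeric model matrix (no intercept), one column per term.
#'   Column names are carried into the result.
#' @param max_iter,tol Newton-Raphson controls.
#' @return List of class `"cox_fit"`: `coef`, `hr`, `se`, `ci_lower`,
#'   `ci_upper`, `p` (named per term), `loglik`, `n`, `n_events`,
#'   `converged`.
#' @details Monotone partial likelihoods (a term that perfectly orders
#'   events) drive coefficients to infinity; this is detected
#'   (`|coef| > 15`) and reported as an error rather than returning a
#'   silently meaningless estimate.
#' @export
cox_fit <- function(time, event, X, max_iter = 30, tol = 1e-9) {
  X <- as.matrix(X)
  stopifnot(length(time) == nrow(X), length(event) == nrow(X),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 2) stop("need at least 2 events")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) stop("constant term(s): ", paste(colnames(X)[const], collapse = ", "))
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- .cox_loglik(beta, time, event, X)$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- .cox_loglik(beta, time, event, X)
    step <- tryCatch(solve(-d$hessian, d$gradient), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix in Cox fit")
    halving <- 0
    repeat {
      beta_new <- beta + drop(step)
      ll_new <- .cox_loglik(beta_new, time, event, X)$loglik
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      halving <- halving + 1
      if (halving > 20) stop("Cox fit failed to improve the partial likelihood")
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; ll_old <- ll_new
    if (max(abs(beta)) > 15)
      stop("monotone partial likelihood: a term separates events perfectly; ",
           "hazard ratio is not identifiable")
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("Cox fit did not converge in ", max_iter, " iterations")
  d <- .cox_loglik(beta, time, event, X)
  var_beta <- solve(-d$hessian)
  se <- sqrt(diag(var_beta))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coef = beta, hr = exp(beta), se = se,
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    loglik = d$loglik, n = nrow(X), n_events = sum(event),
    converged = converged), class = "cox_fit")
}

# Breslow partial log-likelihood with gradient and (negative-definite)
# Hessian. Risk sets computed on times sorted decreasingly so cumulative
# sums give the running denominators.
.cox_loglik <- function(beta, time, event, X) {
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; ee <- event[ord]; Z <- X[ord, , drop = FALSE]
  eta <- drop(Z %*% beta)
  w <- exp(eta)
  S0 <- cumsum(w)
  S1 <- apply(Z * w, 2, cumsum)
  if (is.null(dim(S1))) S1 <- matrix(S1, ncol = ncol(X))
  p <- ncol(X)
  # S2 running sums of w * x x^T, stored as p*p columns
  S2 <- matrix(0, length(tt), p * p)
  for (j in seq_len(p)) for (k in seq_len(p))
    S2[, (j - 1) * p + k] <- cumsum(w * Z[, j] * Z[, k])
  # Breslow: all subjects with time >= t are at risk; with decreasing sort,
  # the risk set for the event at row i is rows 1..last row sharing tt[i]
  last_idx <- cumsum(rle(tt)$lengths)
  idx_of <- rep(last_idx, rle(tt)$lengths)
  ev <- which(ee == 1)
  ri <- idx_of[ev]
  loglik <- sum(eta[ev]) - sum(log(S0[ri]))
  grad <- colSums(Z[ev, , drop = FALSE]) - colSums(S1[ri, , drop = FALSE] / S0[ri])
  hess <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    m2 <- S2[ri, (j - 1) * p + k] / S0[ri]
    m1 <- (S1[ri, j] / S0[ri]) * (S1[ri, k] / S0[ri])
    hess[j, k] <- -sum(m2 - m1)
  }
  list(loglik = loglik, gradient = grad, hessian = hess)
}

#' Multivariate Cox regression on a clinical record table
#'
#' Convenience wrapper around [cox_fit()] that builds the model matrix from
#' a clinical table the way the survival analyses in this pipeline use it:
#' a primary grouping term (CIN cluster with cluster 1 as reference, or
#' methylation decrease group with "Large" as reference) plus the clinical
#' covariates age (dichotomized at 65), gender and TNM stage (ordered
#' categorical with an explicit missing level).
#'
#' @param records Data frame with columns `time`, `event`, plus the columns
#'   named in `group` and `covariates`.
#' @param group Name of the primary grouping column (factor or character);
#'   its first level (after `ref` relocation) is the reference.
#' @param ref Reference level for the grouping term.
#' @param covariates Character vector of covariate column names; recognized
#'   names: `"age"` (numeric, split at > 65), `"gender"`, `"tnm_stage"`.
#' @return A `"cox_fit"` object (see [cox_fit()]).
#' @export
cox_multivariate <- function(records, group, ref = NULL,
                             covariates = c("age", "gender", "tnm_stage")) {
  stopifnot(all(c("time", "event", group) %in% names(records)))
  g <- factor(records[[group]])
  if (!is.null(ref)) g <- stats::relevel(g, ref = as.character(ref))
  X <- .dummy_cols(g, prefix = group)
  for (cv in covariates) {
    if (!cv %in% names(records)) next
    v <- records[[cv]]
    if (cv == "age") {
      X <- cbind(X, age_gt65 = as.numeric(v > 65))
    } else {
      f <- as.character(v)
      f[is.na(f)] <- "missing"
      X <- cbind(X, .dummy_cols(factor(f), prefix = cv))
    }
  }
  # drop covariate columns that are constant in this cohort (e.g. an unused
  # TNM level); a constant primary group term still errors in cox_fit
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  primary <- grepl(paste0("^", group), colnames(X))
  X <- X[, keep | primary, drop = FALSE]
  cox_fit(records$time, records$event, X)
}

.dummy_cols <- function(f, prefix) {
  lv <- levels(f)
  if (length(lv) < 2) stop("grouping term '", prefix, "' has a single level")
  m <- vapply(lv[-1], function(l) as.numeric(f == l), numeric(length(f)))
  m <- matrix(m, nrow = length(f),
              dimnames = list(NULL, paste0(prefix, lv[-1])))
  m
}
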