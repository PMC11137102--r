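#' Minimum cohort size to observe at least one sample of a rare subtype
#'
#' Under a binomial model where each patient independently belongs to the
#' subtype of interest with probability `p_subtype`, returns the smallest
#' cohort size `n` for which the probability of observing at least one such
#' patient, `1 - (1 - p)^n`, reaches `confidence`.
#'
#' With the low-CIN cluster prevalence of 0.1 and 95% confidence this gives
#' 29 patients.
#'
#' @param p_subtype Probability that a single patient belongs to the subtype
#'   (e.g. 0.1 for CIN cluster 1). Must lie in (0, 1].
#' @param confidence Required probability of seeing at least one subtype
#'   patient, in (0, 1).
#' @return Smallest integer `n` with `1 - (1 - p_subtype)^n >= confidence`.
#' @seealso [confidence_at_n()] for the inverse calculation.
#' @export
#' @examples
#' min_samples_binomial(0.1, 0.95)  # 29
min_samples_binomial <- function(p_subtype, confidence) {
  stopifnot(length(p_subtype) == 1L, length(confidence) == 1L)
  if (!is.finite(p_subtype) || p_subtype <= 0 || p_subtype > 1)
    stop("p_subtype must lie in (0, 1]; confidence is unreachable at p = 0")
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  if (p_subtype == 1) return(1L)
  n <- ceiling(log1p(-confidence) / log1p(-p_subtype))
  # guard the ceiling against floating-point grazes of the boundary
  while (confidence_at_n(p_subtype, n - 1) >= confidence) n <- n - 1
  while (confidence_at_n(p_subtype, n) < confidence) n <- n + 1
  as.integer(n)
}

#' Probability of observing at least one subtype patient in a cohort of n
#'
#' @param p_subtype Per-patient subtype probability in \[0, 1\].
#' @param n Cohort size (non-negative integer).
#' @return `1 - (1 - p_subtype)^n`.
#' @export
#' @examples
#' confidence_at_n(0.1, 24)  # ~0.92
confidence_at_n <- function(p_subtype, n) {
  stopifnot(is.finite(p_subtype), p_subtype >= 0, p_subtype <= 1,
            is.finite(n), n >= 0)
  -expm1(n * log1p(-p_subtype))
}

#' Significance stars for a p-value
#'
#' Boxplot annotation convention: `*`, `**`, `***`, `****` at thresholds
#' 0.05, 0.01, 0.001 and 0.0001; `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE) |>
    as.character()
}
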