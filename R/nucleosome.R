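# Nucleosome footprinting: signed distances from cfDNA fragment starts to
# the nearest nucleosome center (the genome-wide "M-shaped" profile) and a
# 0-1 deviation score anchored at mean healthy and mean tumor profiles.

#' Distance profile of fragment starts around nucleosome centers
#'
#' For each read start, the signed distance to the nearest nucleosome
#' center on the same chromosome (`read - center`; ties between equidistant
#' centers break toward the upstream, smaller-coordinate center). Distances
#' are histogrammed into fixed-width bins over `[-window, window)`; reads
#' outside the window are counted but excluded.
#'
#' @param read_starts Data frame `chrom`, `start` of fragment start
#'   coordinates (0-based).
#' @param track Nucleosome track: data frame `chrom`, `pos` of center
#'   coordinates (sorted, unique per chromosome).
#' @param window Half-width of the profile in bp.
#' @param bin_width Histogram bin width in bp (must divide `2 * window`).
#' @return List of class `"distance_profile"`: `breaks` (bin edges),
#'   `mid` (bin midpoints), `fraction` (sums to 1 over in-range reads),
#'   `n_reads` (in range), `n_excluded`.
#' @export
distance_profile <- function(read_starts, track, window = 300, bin_width = 10) {
  if (is.null(read_starts) || nrow(read_starts) == 0) stop("no reads")
  if (is.null(track) || nrow(track) == 0) stop("empty nucleosome track")
  if ((2 * window) %% bin_width != 0)
    stop("bin_width must divide the profile width")
  d <- rep(NA_real_, nrow(read_starts))
  for (ch in unique(read_starts$chrom)) {
    centers <- sort(unique(track$pos[track$chrom == ch]))
    sel <- which(read_starts$chrom == ch)
    if (length(centers) == 0) next
    x <- read_starts$start[sel]
    i <- findInterval(x, centers)          # nearest center at or below x
    lo <- centers[pmax(i, 1)]
    hi <- centers[pmin(i + 1, length(centers))]
    lo[i == 0] <- -Inf
    d_lo <- x - lo; d_hi <- x - hi
    # ties (|d_lo| == |d_hi|) go to the upstream center: strict '<' keeps lo
    use_hi <- abs(d_hi) < abs(d_lo)
    d[sel] <- ifelse(use_hi, d_hi, d_lo)
  }
  in_range <- !is.na(d) & d >= -window & d < window
  breaks <- seq(-window, window, by = bin_width)
  h <- hist(d[in_range], breaks = breaks, plot = FALSE, right = FALSE)
  n_in <- sum(in_range)
  if (n_in == 0) stop("no reads within the profile window")
  structure(list(breaks = breaks, mid = h$mids,
                 fraction = h$counts / n_in,
                 n_reads = n_in,
                 n_excluded = nrow(read_starts) - n_in),
            class = "distance_profile")
}

#' Mean healthy and tumor reference distance profiles
#'
#' Per-bin arithmetic mean of the group's profile fractions, renormalized.
#'
#' @param healthy_profiles,tumor_profiles Non-empty lists of
#'   `distance_profile`s on identical binning.
#' @return List with `healthy` and `tumor` reference `distance_profile`s.
#' @export
reference_profiles <- function(healthy_profiles, tumor_profiles) {
  avg <- function(ps) {
    stopifnot(length(ps) >= 1)
    b <- ps[[1]]$breaks
    for (p in ps) if (!identical(p$breaks, b)) stop("profile binning mismatch")
    f <- rowMeans(vapply(ps, `[[`, numeric(length(ps[[1]]$fraction)), "fraction"))
    structure(list(breaks = b, mid = ps[[1]]$mid, fraction = f / sum(f),
                   n_reads = sum(vapply(ps, `[[`, numeric(1), "n_reads")),
                   n_excluded = sum(vapply(ps, `[[`, numeric(1), "n_excluded"))),
              class = "distance_profile")
  }
  list(healthy = avg(healthy_profiles), tumor = avg(tumor_profiles))
}

#' Nucleosome deviation score
#'
#' Linear projection of the sample's bin-fraction vector onto the
#' healthy-to-tumor axis: `score = <s - h, m - h> / <m - h, m - h>`, so the
#' mean healthy reference scores exactly 0 and the mean tumor (mCRC)
#' reference exactly 1. Values outside \[0, 1\] are legitimate (stronger
#' than either reference) and flagged rather than truncated.
#'
#' @param sample,healthy_ref,tumor_ref `distance_profile`s on identical
#'   binning.
#' @return List of class `"nucleosome_score"`: `score`, `out_of_range`.
#' @export
nucleosome_score <- function(sample, healthy_ref, tumor_ref) {
  if (!identical(sample$breaks, healthy_ref$breaks) ||
      !identical(sample$breaks, tumor_ref$breaks))
    stop("profile binning mismatch")
  axis <- tumor_ref$fraction - healthy_ref$fraction
  denom <- sum(axis^2)
  if (denom == 0) stop("healthy and tumor references are identical")
  score <- sum((sample$fraction - healthy_ref$fraction) * axis) / denom
  structure(list(score = score, out_of_range = score < 0 || score > 1),
            class = "nucleosome_score")
}

#' Correlation between nucleosome scores and tumor fractions
#'
#' Spearman rank correlation with two-sided p-value (see [spearman_cor()]).
#'
#' @param scores,tumor_fractions Paired numeric vectors, n >= 3.
#' @return List `rho`, `p`, `n`.
#' @export
score_tf_correlation <- function(scores, tumor_fractions) {
  spearman_cor(scores, tumor_fractions)
}
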