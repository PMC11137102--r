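# From binned read counts to reference-normalized log2-ratio profiles,
# segments, and a tumor-fraction estimate. These stages are simplified,
# documented analogues of the panel-normalization / segmentation /
# mixture-fit pipeline used for low-coverage WGS copy-number calling.

#' Binned coverage profile
#'
#' @param sample_id Sample identifier.
#' @param bins Data frame `chrom`, `start`, `end` (0-based half-open,
#'   non-overlapping, sorted, fixed width).
#' @param counts Non-negative integer read counts, one per bin.
#' @param gc Optional per-bin GC fraction.
#' @return Object of class `"binned_coverage_profile"`.
#' @export
binned_coverage_profile <- function(sample_id, bins, counts, gc = NULL) {
  stopifnot(nrow(bins) == length(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  r <- rle(as.character(bins$chrom))
  if (anyDuplicated(r$values))
    stop("bins of one chromosome must form a contiguous block")
  if (any(tapply(bins$start, factor(bins$chrom, unique(bins$chrom)), is.unsorted)))
    stop("bins must be sorted by start within each chromosome")
  structure(list(sample_id = sample_id, bins = bins,
                 counts = as.numeric(counts), gc = gc,
                 total_reads = sum(counts)),
            class = "binned_coverage_profile")
}

.check_same_grid <- function(a_bins, b_bins) {
  if (nrow(a_bins) != nrow(b_bins) ||
      !all(a_bins$chrom == b_bins$chrom) ||
      !all(a_bins$start == b_bins$start))
    stop("bin grids do not match")
}

#' Build a healthy reference panel from coverage profiles
#'
#' Depth-normalizes each healthy profile (counts divided by total), then
#' records the per-bin median (location) and MAD (scale) across samples.
#' Bins with zero median, or whose relative MAD exceeds `mad_outlier`, are
#' blacklisted and excluded from all downstream statistics.
#'
#' @param healthy_profiles List of at least 3 `binned_coverage_profile`s on
#'   an identical bin grid.
#' @param mad_outlier Blacklist a bin when `MAD / median` exceeds this.
#' @return List of class `"reference_panel"`: `bins`, `location`, `scale`,
#'   `blacklist` (logical), `sample_ids`.
#' @export
build_reference_panel <- function(healthy_profiles, mad_outlier = 0.5) {
  if (length(healthy_profiles) < 3)
    stop("need at least 3 healthy profiles")
  bins <- healthy_profiles[[1]]$bins
  for (p in healthy_profiles) .check_same_grid(bins, p$bins)
  norm <- vapply(healthy_profiles, function(p) p$counts / sum(p$counts),
                 numeric(nrow(bins)))
  location <- apply(norm, 1, stats::median)
  scale <- apply(norm, 1, stats::mad)
  blacklist <- location == 0 | (location > 0 & scale / location > mad_outlier)
  structure(list(bins = bins, location = location, scale = scale,
                 blacklist = blacklist,
                 sample_ids = vapply(healthy_profiles, `[[`, "", "sample_id")),
            class = "reference_panel")
}

#' Normalize a coverage profile against the reference panel
#'
#' Depth-normalizes the sample over unmasked bins and reports per-bin log2
#' ratios against the panel location (both renormalized to the unmasked
#' bins) and z-scores against the panel scale. With `recenter = TRUE`
#' (default) the log2 ratios are shifted so their median over unmasked
#' bins is 0, anchoring the copy-neutral state at ratio 0 even when
#' aneuploidy moves the sample's mean ploidy away from 2 (total-count
#' normalization alone would otherwise shift every bin). Zero-count bins
#' cannot carry a finite log ratio and are masked for this sample.
#'
#' @param sample A `binned_coverage_profile` on the panel's grid.
#' @param panel A `reference_panel`.
#' @param recenter Anchor the median unmasked log2 ratio at 0.
#' @return List of class `"log_ratio_profile"`: `sample_id`, `bins`,
#'   `log2_ratio`, `z`, `mask` (TRUE = excluded).
#' @export
normalize_profile <- function(sample, panel, recenter = TRUE) {
  .check_same_grid(sample$bins, panel$bins)
  if (sum(sample$counts) == 0) stop("all-zero sample cannot be normalized")
  mask <- panel$blacklist | sample$counts == 0
  um <- !mask
  x <- sample$counts / sum(sample$counts[um])
  loc <- panel$location / sum(panel$location[um])
  lr <- z <- rep(NA_real_, length(x))
  lr[um] <- log2(x[um] / loc[um])
  if (recenter) lr[um] <- lr[um] - stats::median(lr[um])
  scl <- panel$scale / sum(panel$location[um])
  z[um] <- ifelse(scl[um] > 0, (x[um] - loc[um]) / scl[um], 0)
  structure(list(sample_id = sample$sample_id, bins = sample$bins,
                 log2_ratio = lr, z = z, mask = mask),
            class = "log_ratio_profile")
}

#' Segment a log2-ratio profile by recursive binary splitting
#'
#' Within each chromosome, the unmasked bins are split recursively at the
#' position maximizing a two-sample t-like statistic (difference of means
#' over a pooled standard deviation); a split is accepted when the
#' statistic exceeds `split_threshold` and both halves retain at least
#' `min_segment_bins` bins. A simplified stand-in for circular binary
#' segmentation.
#'
#' @param lrp A `log_ratio_profile`.
#' @param min_segment_bins Minimum bins per segment.
#' @param split_threshold t-statistic needed to accept a split.
#' @param calling_threshold `|mean log2 ratio|` above which a segment
#'   counts as altered for the genome-altered fraction.
#' @return List of class `"segmented_cna_profile"`: `sample_id`, `segments`
#'   (data.frame chrom, start_bin, end_bin (half-open global 0-based bin
#'   indices), start, end (genomic), mean_lr, n_bins),
#'   `genome_altered_fraction`, `n_unmasked`, `calling_threshold`, `bins`,
#'   `mask`.
#' @export
segment_profile <- function(lrp, min_segment_bins = 5, split_threshold = 5,
                            calling_threshold = 0.1) {
  um_idx <- which(!lrp$mask)
  if (length(um_idx) < min_segment_bins)
    stop("fewer unmasked bins than min_segment_bins")
  segs <- list()
  for (ch in unique(lrp$bins$chrom)) {
    idx <- um_idx[lrp$bins$chrom[um_idx] == ch]
    if (length(idx) == 0) next
    vals <- lrp$log2_ratio[idx]
    bounds <- .rbs_segment(vals, min_segment_bins, split_threshold)
    for (b in seq_len(nrow(bounds))) {
      sel <- idx[bounds[b, 1]:bounds[b, 2]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch,
        start_bin = sel[1] - 1L, end_bin = sel[length(sel)],
        start = lrp$bins$start[sel[1]], end = lrp$bins$end[sel[length(sel)]],
        mean_lr = mean(lrp$log2_ratio[sel]), n_bins = length(sel))
    }
  }
  segments <- do.call(rbind, segs)
  altered <- abs(segments$mean_lr) > calling_threshold
  gaf <- sum(segments$n_bins[altered]) / sum(segments$n_bins)
  structure(list(sample_id = lrp$sample_id, segments = segments,
                 genome_altered_fraction = gaf,
                 n_unmasked = length(um_idx),
                 calling_threshold = calling_threshold,
                 bins = lrp$bins, mask = lrp$mask),
            class = "segmented_cna_profile")
}

# Recursive segmentation over a numeric vector; returns a matrix of
# (first, last) index pairs partitioning 1..n. Each round considers both a
# single boundary split and interior windows (window-vs-rest, over a
# geometric ladder of widths), so a short event inside a long segment is
# found even when a single-boundary statistic would be diluted by the
# flanks — the property that motivates circular binary segmentation.
.rbs_segment <- function(vals, min_bins, threshold) {
  out <- list()
  recurse <- function(lo, hi) {
    n_seg <- hi - lo + 1
    if (n_seg < 2 * min_bins) {
      out[[length(out) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    v <- vals[lo:hi]
    best <- .best_split(v, min_bins)
    if (!is.null(best) && best$t > threshold) {
      cuts <- lo - 1 + best$bounds        # last indices of the sub-parts
      prev <- lo
      for (cut in cuts) {
        recurse(prev, cut)
        prev <- cut + 1
      }
      if (prev <= hi) recurse(prev, hi)
    } else {
      out[[length(out) + 1L]] <<- c(lo, hi)
    }
    invisible()
  }
  recurse(1, length(vals))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

# best change-point(s) of a segment: the stronger of the best single
# boundary split and the best interior window; returns NULL when the
# segment admits no candidate
.best_split <- function(v, min_bins) {
  n <- length(v)
  cs <- cumsum(v); css <- cumsum(v^2)
  tot <- cs[n]; tot2 <- css[n]
  sp2_of <- function(ss_in, ss_out) pmax((ss_in + ss_out) / pmax(n - 2, 1), 1e-12)
  best <- NULL
  # single boundary
  k <- min_bins:(n - min_bins)
  if (length(k) > 0) {
    n1 <- k; n2 <- n - k
    m1 <- cs[k] / n1; m2 <- (tot - cs[k]) / n2
    ss1 <- css[k] - n1 * m1^2
    ss2 <- (tot2 - css[k]) - n2 * m2^2
    tstat <- abs(m1 - m2) / sqrt(sp2_of(ss1, ss2) * (1 / n1 + 1 / n2))
    i <- which.max(tstat)
    best <- list(t = tstat[i], bounds = k[i])
  }
  # interior windows, all widths up to a cap (wider events present enough
  # contrast at a single boundary to be found by the split above)
  widths <- min_bins:min(n - min_bins, 300)
  cs0 <- c(0, cs); css0 <- c(0, css)
  for (w in widths) {
    starts <- seq_len(n - w + 1)          # window = starts .. starts+w-1
    s_in <- cs0[starts + w] - cs0[starts]
    ss_in_raw <- css0[starts + w] - css0[starts]
    n_out <- n - w
    m_in <- s_in / w; m_out <- (tot - s_in) / n_out
    ss_in <- ss_in_raw - w * m_in^2
    ss_out <- (tot2 - ss_in_raw) - n_out * m_out^2
    tstat <- abs(m_in - m_out) / sqrt(sp2_of(ss_in, ss_out) * (1 / w + 1 / n_out))
    # flanks must be empty or at least min_bins wide
    left <- starts - 1
    ok <- (left == 0 | left >= min_bins) &
      (n - (starts + w - 1) == 0 | n - (starts + w - 1) >= min_bins)
    tstat[!ok] <- -Inf
    j <- which.max(tstat)
    if (is.finite(tstat[j]) && (is.null(best) || tstat[j] > best$t)) {
      bounds <- c(if (left[j] > 0) left[j], left[j] + w)
      bounds <- bounds[bounds < n]
      if (length(bounds) > 0) best <- list(t = tstat[j], bounds = bounds)
    }
  }
  best
}

#' Estimate tumor fraction from a segmented profile
#'
#' Grid search over candidate tumor fractions: at each `tf`, every segment
#' is assigned the integer copy number in `cn_states` whose expected log2
#' ratio `log2((2 (1 - tf) + tf CN) / 2)` is closest to the observed
#' segment mean; the bin-weighted squared error selects the best `tf`.
#' Among near-ties (within `tie_tol` relative error) the smallest `tf`
#' wins, a conservative guard against purity/ploidy aliasing. A profile
#' with no altered segments returns `tf = 0`.
#'
#' @param seg A `segmented_cna_profile`.
#' @param tf_grid Candidate tumor fractions (default 0 to 1 step 0.01).
#' @param cn_states Integer copy-number states considered.
#' @param tie_tol Relative error within which fits count as tied.
#' @return List of class `"tumor_fraction_estimate"`: `tf`, `fit_error`
#'   (bin-weighted mean squared error), `segment_cn` (inferred copy number
#'   per segment at the chosen `tf`).
#' @export
estimate_tumor_fraction <- function(seg, tf_grid = seq(0, 1, by = 0.01),
                                    cn_states = 0:4, tie_tol = 1e-9) {
  if (length(tf_grid) == 0) stop("empty tumor-fraction grid")
  if (any(tf_grid < 0 | tf_grid > 1)) stop("tf_grid must lie within [0, 1]")
  segments <- seg$segments
  if (nrow(segments) == 0) stop("no segments")
  obs <- segments$mean_lr; w <- segments$n_bins
  if (all(abs(obs) < 1e-12)) {
    return(structure(list(tf = 0, fit_error = sum(w * obs^2) / sum(w),
                          segment_cn = rep(2L, nrow(segments))),
                     class = "tumor_fraction_estimate"))
  }
  best <- NULL
  for (tf in sort(tf_grid)) {
    mix <- (2 * (1 - tf) + tf * cn_states) / 2
    exp_lr <- log2(pmax(mix, 1e-6))
    dm <- abs(outer(obs, exp_lr, "-"))
    pick <- apply(dm, 1, which.min)
    err <- sum(w * (obs - exp_lr[pick])^2) / sum(w)
    if (is.null(best) || err < best$err * (1 - tie_tol)) {
      best <- list(tf = tf, err = err, cn = cn_states[pick])
    }
  }
  structure(list(tf = best$tf, fit_error = best$err,
                 segment_cn = as.integer(best$cn)),
            class = "tumor_fraction_estimate")
}
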