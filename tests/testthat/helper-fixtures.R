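# Shared fixtures, built once per test run. Sizes are kept small; the
# full-size study conditions are exercised in the acceptance suite.

fix_cfg <- cohort_config(seed = 101)
fix_arch <- generate_cluster_archetypes(fix_cfg)

fix_panel <- local({
  set.seed(900)
  healthy <- lapply(1:10, function(i)
    simulate_binned_reads(rep(2L, nrow(fix_arch$bins)), 0,
                          fix_cfg$reads_per_sample, fix_arch$bins,
                          nb_size = fix_cfg$nb_size,
                          sample_id = sprintf("H%02d", i)))
  build_reference_panel(healthy)
})

# a tiny flat genome for constructed (non-simulated) profiles
flat_bins <- function(n = 200, width = 1000) {
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * width,
             end = seq_len(n) * width)
}

flat_panel <- function(n_bins = 200, counts = 100, n_samples = 5) {
  bins <- flat_bins(n_bins)
  build_reference_panel(lapply(seq_len(n_samples), function(i)
    binned_coverage_profile(sprintf("h%d", i), bins,
                            rep(counts, n_bins))))
}

# segmented profile assembled directly from a piecewise description;
# bypasses simulation for exact-arithmetic tests
manual_segments <- function(level_runs, calling_threshold = 0.1,
                            chrom = "chr1", bin_width = 1000) {
  n <- sum(vapply(level_runs, `[[`, numeric(1), "n"))
  bins <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin_width,
                     end = seq_len(n) * bin_width)
  pos <- 0L
  segs <- lapply(level_runs, function(r) {
    s <- data.frame(chrom = chrom, start_bin = pos, end_bin = pos + r$n,
                    start = pos * bin_width, end = (pos + r$n) * bin_width,
                    mean_lr = r$level, n_bins = r$n)
    pos <<- pos + as.integer(r$n)
    s
  })
  segments <- do.call(rbind, segs)
  altered <- abs(segments$mean_lr) > calling_threshold
  structure(list(sample_id = "manual", segments = segments,
                 genome_altered_fraction =
                   sum(segments$n_bins[altered]) / sum(segments$n_bins),
                 n_unmasked = n, calling_threshold = calling_threshold,
                 bins = bins, mask = rep(FALSE, n)),
            class = "segmented_cna_profile")
}

# distance_profile object built from a fraction vector (for exact score
# arithmetic)
manual_profile <- function(fraction, window = 300, bin_width = 10) {
  breaks <- seq(-window, window, by = bin_width)
  structure(list(breaks = breaks, mid = breaks[-1] - bin_width / 2,
                 fraction = fraction / sum(fraction),
                 n_reads = 1e6, n_excluded = 0),
            class = "distance_profile")
}
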