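# Synthetic paired tissue/plasma cohort with known ground truth. Every
# downstream stage (normalization, segmentation, tumor-fraction fitting,
# CIN classification, nucleosome scoring, methylation scoring, survival) is
# exercised against cohorts produced here.

#' Generate CIN cluster archetypes: peak regions, templates and centroids
#'
#' Lays out `n_amp_peaks` amplification and `n_del_peaks` deletion peak
#' regions (non-overlapping, 0-based half-open bin intervals) across the
#' synthetic genome and builds three integer copy-number templates:
#' cluster 1 is near-diploid (a handful of weak/focal events), clusters 2
#' and 3 alter many peaks with partially overlapping but distinguishable
#' patterns. Each peak sits at the center of a wider alteration "event"
#' (arm-like for single-copy events, focal for two-copy events), which is
#' what gets gained or lost in a template carrying that peak.
#'
#' @param config A [cohort_config()].
#' @return List with `peaks` (data.frame: chrom, start, end, label,
#'   direction, bin_start, bin_end, event_bin_start, event_bin_end, alt_cn),
#'   `templates` (3 x n_bins integer matrix of copy numbers, rows =
#'   clusters), `centroids` (3 x n_peaks matrix of expected log2 ratios at
#'   tumor fraction 1), `bins`, and `altered_sets` (per-cluster peak index
#'   sets).
#' @export
generate_cluster_archetypes <- function(config) {
  set.seed(config$seed)
  bins <- make_bins(config)
  nb <- nrow(bins)
  n_amp <- config$n_amp_peaks; n_del <- config$n_del_peaks
  n_peaks <- n_amp + n_del
  per_chr <- nb / config$n_chrom

  if (n_peaks == 0) {
    peaks <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), label = character(0),
                        direction = character(0), bin_start = integer(0),
                        bin_end = integer(0), event_bin_start = integer(0),
                        event_bin_end = integer(0), alt_cn = integer(0))
    templates <- matrix(2L, 3, nb)
    centroids <- matrix(numeric(0), 3, 0)
    rownames(templates) <- rownames(centroids) <- paste0("cluster", 1:3)
    return(list(peaks = peaks, templates = templates, centroids = centroids,
                bins = bins, altered_sets = list(integer(0), integer(0), integer(0))))
  }

  direction <- c(rep("amp", n_amp), rep("del", n_del))
  # ~30% of peaks are focal two-copy events (CN 4 / CN 0), the rest broad
  # single-copy events (CN 3 / CN 1); both families are needed to make the
  # tumor-fraction fit identifiable (a genome of only single-copy events
  # aliases with half the copy change at twice the tumor fraction)
  focal <- rep(FALSE, n_peaks)
  focal[c(sample(which(direction == "amp"), max(1, round(0.3 * n_amp))),
          sample(which(direction == "del"), max(1, round(0.3 * n_del))))] <- TRUE
  span <- ifelse(focal, sample(12:20, n_peaks, replace = TRUE),
                 sample(26:40, n_peaks, replace = TRUE))
  alt_cn <- ifelse(direction == "amp", ifelse(focal, 4L, 3L),
                   ifelse(focal, 0L, 1L))

  # sequential placement along the genome with neutral gaps, never crossing
  # a chromosome boundary
  ord <- sample.int(n_peaks)
  ev_start <- integer(n_peaks); ev_end <- integer(n_peaks)
  pos <- 0
  for (i in ord) {
    gap <- sample(6:12, 1)
    s <- pos + gap
    # move to the next chromosome if the event would straddle a boundary
    if ((s %/% per_chr) != ((s + span[i] - 1) %/% per_chr)) {
      s <- (s %/% per_chr + 1) * per_chr + 2
    }
    e <- s + span[i]
    if (e > nb)
      stop("genome too small to host ", n_peaks, " peak regions: ",
           "increase n_bins or reduce peak counts")
    ev_start[i] <- s; ev_end[i] <- e
    pos <- e
  }
  # peak region: central 5 bins of the event
  mid <- (ev_start + ev_end) %/% 2
  pk_start <- pmax(ev_start, mid - 2L)
  pk_end <- pmin(ev_end, pk_start + 5L)

  label <- c(sprintf("amp_%02d", seq_len(n_amp)),
             if (n_del > 0) sprintf("del_%02d", seq_len(n_del)))
  peaks <- data.frame(
    chrom = bins$chrom[pk_start + 1L],
    start = bins$start[pk_start + 1L],
    end = bins$end[pk_end],       # pk_end is half-open in bin index
    label = label, direction = direction,
    bin_start = pk_start, bin_end = pk_end,
    event_bin_start = ev_start, event_bin_end = ev_end,
    alt_cn = alt_cn, stringsAsFactors = FALSE)

  amp_idx <- which(direction == "amp"); del_idx <- which(direction == "del")
  amp_focal <- intersect(amp_idx, which(focal)); amp_broad <- setdiff(amp_idx, amp_focal)
  del_focal <- intersect(del_idx, which(focal)); del_broad <- setdiff(del_idx, del_focal)

  pick <- function(pool, k) if (k <= 0) integer(0) else
    pool[sample.int(length(pool), min(k, length(pool)))]

  # cluster 1: near-diploid, 4 weak events (one of each family so its tumor
  # fraction is still identifiable)
  set1 <- c(pick(amp_focal, 1), pick(amp_broad, 1),
            pick(del_focal, 1), pick(del_broad, 1))
  # cluster 2: many events
  set2 <- c(pick(amp_focal, 7), pick(amp_broad, 17),
            pick(del_focal, 10), pick(del_broad, 25))
  # cluster 3: similar burden, roughly half shared with cluster 2
  shared <- c(pick(intersect(set2, amp_idx), 12), pick(intersect(set2, del_idx), 17))
  own_pool_amp <- setdiff(amp_idx, set2); own_pool_del <- setdiff(del_idx, set2)
  set3 <- c(shared, pick(own_pool_amp, 12), pick(own_pool_del, 18))
  altered_sets <- list(sort(unique(set1)), sort(unique(set2)), sort(unique(set3)))

  templates <- matrix(2L, 3, nb)
  centroids <- matrix(0, 3, n_peaks)
  for (k in 1:3) {
    for (i in altered_sets[[k]]) {
      templates[k, (ev_start[i] + 1L):ev_end[i]] <- alt_cn[i]
      centroids[k, i] <- log2(max(alt_cn[i], 0.1) / 2)
    }
  }
  rownames(templates) <- rownames(centroids) <- paste0("cluster", 1:3)
  colnames(centroids) <- label
  list(peaks = peaks, templates = templates, centroids = centroids,
       bins = bins, altered_sets = altered_sets)
}

#' Simulate binned read counts for one sample
#'
#' Per-bin counts are drawn from a negative binomial whose mean is
#' proportional to `gc_bias * (2 * (1 - tf) + tf * CN) / 2` — the standard
#' two-component mixture of diploid non-tumor and aneuploid tumor DNA —
#' normalized so the expected total equals `reads`.
#'
#' @param template Integer copy number per bin (non-negative).
#' @param tumor_fraction Tumor fraction in \[0, 1\].
#' @param reads Expected total read count.
#' @param bins Bin grid data frame (see [make_bins()]).
#' @param gc_bias Optional per-bin multiplicative factor (default flat).
#' @param nb_size Negative-binomial dispersion; `Inf` for Poisson.
#' @param sample_id Sample identifier.
#' @param seed Optional seed (set only when supplied).
#' @return A `binned_coverage_profile` (see [binned_coverage_profile()]).
#' @export
simulate_binned_reads <- function(template, tumor_fraction, reads, bins,
                                  gc_bias = NULL, nb_size = 2000,
                                  sample_id = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  template <- as.numeric(template)
  if (any(template < 0) || any(template != round(template)))
    stop("copy-number template must contain non-negative integers")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  stopifnot(reads > 0, length(template) == nrow(bins))
  if (is.null(gc_bias)) gc_bias <- rep(1, length(template))
  mixture <- (2 * (1 - tumor_fraction) + tumor_fraction * template) / 2
  mu <- gc_bias * mixture
  mu <- reads * mu / sum(mu)
  counts <- if (is.infinite(nb_size)) stats::rpois(length(mu), mu)
            else stats::rnbinom(length(mu), mu = mu, size = nb_size)
  binned_coverage_profile(sample_id, bins, counts, gc = NULL)
}

#' Default nucleosome-offset distributions
#'
#' Discrete distributions of the signed offset between a cfDNA fragment
#' start and the center of the nucleosome it derives from. The healthy
#' distribution is symmetric bimodal with modes near +/-73 bp (fragment
#' starts flank the protected core, giving the M-shaped distance profile);
#' the tumor distribution is flatter and center-shifted, so tumor-derived
#' reads are relatively enriched at nucleosome centers.
#'
#' @param window Maximum absolute offset modelled (bp).
#' @param healthy_sd,tumor_sd Spread of the component normals.
#' @return List with `healthy` and `tumor`, each `list(offsets, probs)`.
#' @export
nucleosome_offset_dists <- function(window = 300, healthy_sd = 30, tumor_sd = 110) {
  offsets <- seq(-window + 1, window - 1)
  h <- 0.5 * stats::dnorm(offsets, -73, healthy_sd) +
       0.5 * stats::dnorm(offsets, 73, healthy_sd)
  t <- stats::dnorm(offsets, 0, tumor_sd)
  list(healthy = list(offsets = offsets, probs = h / sum(h)),
       tumor = list(offsets = offsets, probs = t / sum(t)))
}

#' Default synthetic nucleosome-center track
#'
#' Well-separated nucleosome centers on a dedicated coordinate system, so
#' that offsets within the scoring window are unambiguous about which
#' center they derive from.
#'
#' @param n_centers Number of centers.
#' @param spacing Center-to-center distance (bp).
#' @param chrom Chromosome name used for the track.
#' @return Data frame `chrom`, `pos` (0-based center coordinates), sorted.
#' @export
make_nucleosome_track <- function(n_centers = 5000, spacing = 800,
                                  chrom = "chrN") {
  data.frame(chrom = chrom, pos = seq_len(n_centers) * spacing)
}

#' Simulate cfDNA fragment start coordinates around nucleosome centers
#'
#' Each fragment picks a nucleosome center uniformly, then an offset from
#' the healthy distribution with probability `1 - tumor_fraction` and from
#' the tumor distribution with probability `tumor_fraction`.
#'
#' @param tumor_fraction Mixture weight of the tumor component in \[0, 1\].
#' @param n_fragments Number of fragment starts to draw.
#' @param track Nucleosome track (data frame `chrom`, `pos`).
#' @param healthy_offset_dist,tumor_offset_dist Offset distributions
#'   (`list(offsets, probs)`); defaults from [nucleosome_offset_dists()].
#' @param seed Optional seed.
#' @return Data frame `chrom`, `start` of fragment start coordinates.
#' @export
simulate_fragment_starts <- function(tumor_fraction, n_fragments, track,
                                     healthy_offset_dist = NULL,
                                     tumor_offset_dist = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  if (is.null(track) || nrow(track) == 0) stop("empty nucleosome track")
  dists <- nucleosome_offset_dists()
  if (is.null(healthy_offset_dist)) healthy_offset_dist <- dists$healthy
  if (is.null(tumor_offset_dist)) tumor_offset_dist <- dists$tumor
  ci <- sample.int(nrow(track), n_fragments, replace = TRUE)
  from_tumor <- stats::runif(n_fragments) < tumor_fraction
  off <- integer(n_fragments)
  n_t <- sum(from_tumor)
  if (n_t > 0)
    off[from_tumor] <- sample(tumor_offset_dist$offsets, n_t, replace = TRUE,
                              prob = tumor_offset_dist$probs)
  if (n_t < n_fragments)
    off[!from_tumor] <- sample(healthy_offset_dist$offsets, n_fragments - n_t,
                               replace = TRUE, prob = healthy_offset_dist$probs)
  data.frame(chrom = track$chrom[ci], start = track$pos[ci] + off)
}

#' Simulate targeted bisulfite methylation for a cohort
#'
#' Target regions are near-unmethylated in healthy plasma (region baseline
#' betas with mean < 0.03) and hypermethylated in the tumor component.
#' Observed betas are the tumor-fraction mixture
#' `(1 - tf) * beta_healthy + tf * beta_tumor` plus bounded noise.
#' Responders' tumor-component betas drop by `treatment_effect` between the
#' baseline and on-treatment draw.
#'
#' @param tf_pre,tf_post Per-patient tumor fractions at baseline and
#'   on-treatment (equal length, values in \[0, 1\]).
#' @param responder Logical vector: does the tumor methylation respond.
#' @param n_regions Number of target regions.
#' @param tumor_level Per-patient mean tumor-component methylation level;
#'   default drawn from N(0.55, 0.12) clipped to \[0.1, 0.95\].
#' @param treatment_effect Mean beta drop in responders.
#' @param noise_sd Bounded observation noise per sample x region, emulating
#'   binomial sampling of betas at moderate coverage (0 gives the exact
#'   mixture).
#' @param indiv_sd Per-individual baseline methylation offset shared across
#'   regions (inter-individual variability of the healthy component).
#' @param n_healthy Healthy reference samples to draw.
#' @param seed Optional seed.
#' @return List: `healthy` (matrix n_healthy x regions), `pre`, `post`
#'   (patients x regions observed betas), `tumor_pre`, `tumor_post` (true
#'   tumor-component betas), `healthy_ref` (per-region healthy mean),
#'   `region_base` (per-region healthy baseline), `true_delta` (per-patient
#'   mean tumor-component beta change).
#' @export
simulate_methylation <- function(tf_pre, tf_post, responder, n_regions = 200,
                                 tumor_level = NULL, treatment_effect = 0.15,
                                 noise_sd = 0.04, indiv_sd = 0.01,
                                 n_healthy = 41, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(length(tf_pre) == length(tf_post),
            length(responder) == length(tf_pre))
  if (any(c(tf_pre, tf_post) < 0) || any(c(tf_pre, tf_post) > 1))
    stop("tumor fractions must lie in [0, 1]")
  n <- length(tf_pre)
  # healthy baseline per region: Beta with mean 0.015 (design constraint:
  # mean healthy beta < 0.03)
  region_base <- stats::rbeta(n_regions, 0.6, 39.4)
  # tumor hypermethylation varies by region around the per-sample level
  region_effect <- stats::rnorm(n_regions, 0, 0.15)
  if (is.null(tumor_level))
    tumor_level <- pmin(0.95, pmax(0.1, stats::rnorm(n, 0.55, 0.12)))
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  noise <- function(nr, nc) if (noise_sd > 0)
    matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc) else 0

  indiv <- function(k) if (indiv_sd > 0 && noise_sd > 0)
    stats::rnorm(k, 0, indiv_sd) else numeric(k)
  healthy <- clip01(matrix(region_base, n_healthy, n_regions, byrow = TRUE) +
                      indiv(n_healthy) + noise(n_healthy, n_regions))
  tumor_pre <- clip01(outer(tumor_level, rep(1, n_regions)) +
                        matrix(region_effect, n, n_regions, byrow = TRUE) +
                        noise(n, n_regions) * 2)
  tumor_post <- clip01(tumor_pre - treatment_effect * responder)
  base_m <- matrix(region_base, n, n_regions, byrow = TRUE)
  indiv_pat <- indiv(n)
  pre <- clip01((1 - tf_pre) * base_m + tf_pre * tumor_pre + indiv_pat +
                  noise(n, n_regions))
  post <- clip01((1 - tf_post) * base_m + tf_post * tumor_post + indiv_pat +
                   noise(n, n_regions))
  rn <- sprintf("region_%03d", seq_len(n_regions))
  colnames(healthy) <- colnames(pre) <- colnames(post) <-
    colnames(tumor_pre) <- colnames(tumor_post) <- rn
  list(healthy = healthy, pre = pre, post = post,
       tumor_pre = tumor_pre, tumor_post = tumor_post,
       healthy_ref = colMeans(healthy), region_base = region_base,
       true_delta = rowMeans(tumor_post - tumor_pre))
}

#' Simulate proportional-hazards survival records
#'
#' Event times are exponential with a per-patient hazard multiplied by
#' `hr_cluster_high` for clusters 2/3 and by `hr_large_decrease` for
#' patients whose methylation delta lies below the cohort median.
#' Censoring is independent exponential, calibrated so roughly
#' `censoring_rate` of records are censored.
#'
#' @param cluster_labels Integer cluster labels in \{1, 2, 3\}.
#' @param methylation_deltas Optional per-patient methylation score deltas;
#'   `NULL` drops the term.
#' @param baseline_hazard Baseline hazard per day.
#' @param hr_cluster_high,hr_large_decrease Hazard ratios (> 0).
#' @param censoring_rate Target censored fraction in \[0, 1\]; 1 censors all.
#' @param seed Optional seed.
#' @return Data frame `patient_id`, `time` (days), `event`.
#' @export
simulate_survival <- function(cluster_labels, methylation_deltas = NULL,
                              baseline_hazard = 1 / 500,
                              hr_cluster_high = 0.25,
                              hr_large_decrease = 0.4,
                              censoring_rate = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(hr_cluster_high > 0, hr_large_decrease > 0, baseline_hazard > 0)
  n <- length(cluster_labels)
  hz <- rep(baseline_hazard, n)
  hz[cluster_labels %in% c(2, 3)] <- hz[cluster_labels %in% c(2, 3)] * hr_cluster_high
  if (!is.null(methylation_deltas)) {
    large <- methylation_deltas < stats::median(methylation_deltas)
    hz[large] <- hz[large] * hr_large_decrease
  }
  t_event <- stats::rexp(n, hz)
  if (censoring_rate >= 1) {
    return(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      time = t_event, event = 0L))
  }
  if (censoring_rate <= 0) {
    return(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      time = t_event, event = 1L))
  }
  cens_rate <- mean(hz) * censoring_rate / (1 - censoring_rate)
  t_cens <- stats::rexp(n, cens_rate)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Generate the full synthetic paired cohort
#'
#' Orchestrates all generators into one cohort object carrying every
#' ground-truth quantity: cluster archetypes, healthy reference panel,
#' paired tissue/plasma coverage profiles, nucleosome fragment sets with
#' reference healthy/tumor sets, baseline and on-treatment methylation, and
#' survival records for OS and PFS linked to cluster and methylation
#' response.
#'
#' @param config A [cohort_config()].
#' @param components Character vector choosing which data types to
#'   generate: any of `"coverage"`, `"nucleosome"`, `"methylation"`,
#'   `"survival"`.
#' @return List of class `"cfcin_cohort"`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            components = c("coverage", "nucleosome",
                                           "methylation", "survival")) {
  arch <- generate_cluster_archetypes(config)
  set.seed(config$seed + 1L)
  n <- config$n_patients
  cluster <- sample.int(3, n, replace = TRUE, prob = config$cluster_probs)
  tf_tissue <- stats::runif(n, config$tissue_tf_range[1], config$tissue_tf_range[2])
  tf_tissue[cluster == 1] <- tf_tissue[cluster == 1] * config$cluster1_tf_factor
  tf_plasma <- pmin(1, tf_tissue * config$plasma_to_tissue_tf_ratio)
  truth <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cluster = cluster, tf_tissue = tf_tissue, tf_plasma = tf_plasma,
    age = round(stats::runif(n, 45, 80)),
    gender = sample(c("M", "F"), n, replace = TRUE),
    tnm_stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                       prob = c(0.1, 0.3, 0.6)),
    stringsAsFactors = FALSE)
  out <- list(config = config, bins = arch$bins, peaks = arch$peaks,
              templates = arch$templates, centroids = arch$centroids,
              truth = truth)

  if ("coverage" %in% components) {
    set.seed(config$seed + 2L)
    neutral <- rep(2L, nrow(arch$bins))
    out$healthy_profiles <- lapply(seq_len(config$n_healthy), function(i)
      simulate_binned_reads(neutral, 0, config$reads_per_sample, arch$bins,
                            nb_size = config$nb_size,
                            sample_id = sprintf("H%03d", i)))
    out$tissue_profiles <- lapply(seq_len(n), function(i)
      simulate_binned_reads(arch$templates[cluster[i], ], tf_tissue[i],
                            config$reads_per_sample, arch$bins,
                            nb_size = config$nb_size,
                            sample_id = sprintf("P%03d_tissue", i)))
    out$plasma_profiles <- lapply(seq_len(n), function(i)
      simulate_binned_reads(arch$templates[cluster[i], ], tf_plasma[i],
                            config$reads_per_sample, arch$bins,
                            nb_size = config$nb_size,
                            sample_id = sprintf("P%03d_plasma", i)))
  }

  if ("nucleosome" %in% components) {
    set.seed(config$seed + 3L)
    track <- make_nucleosome_track()
    het <- ifelse(cluster == 3 &
                    stats::runif(n) < config$cluster3_nf_het_prob,
                  config$cluster3_nf_het_factor, 1)
    nf_weight <- pmin(1, pmax(0, het * tf_plasma +
                                stats::rnorm(n, 0, config$nf_noise_sd)))
    out$truth$nf_weight <- nf_weight
    out$nucleosome <- list(
      track = track,
      fragments = lapply(seq_len(n), function(i)
        simulate_fragment_starts(nf_weight[i], config$n_fragments, track)),
      healthy_ref_fragments = lapply(1:8, function(i)
        simulate_fragment_starts(0, config$n_fragments, track)),
      tumor_ref_fragments = lapply(1:4, function(i)
        simulate_fragment_starts(1, config$n_fragments, track)))
  }

  if ("methylation" %in% components) {
    set.seed(config$seed + 4L)
    responder <- stats::runif(n) < config$responder_prob
    tf_post <- pmin(1, tf_plasma * stats::runif(n, 0.4, 1.05))
    # tumor methylation level is cluster-linked: low-CIN (cluster 1)
    # tumors are less methylated at the target regions
    tumor_level <- pmin(0.95, pmax(0.1, stats::rnorm(
      n, ifelse(cluster == 1, 0.45, 0.62), 0.10)))
    out$methylation <- simulate_methylation(
      tf_pre = tf_plasma, tf_post = tf_post, responder = responder,
      n_regions = config$n_meth_regions, tumor_level = tumor_level,
      treatment_effect = config$treatment_effect,
      noise_sd = config$meth_noise_sd, indiv_sd = config$meth_indiv_sd,
      n_healthy = config$n_healthy_meth)
    out$truth$responder <- responder
    out$truth$tf_plasma_post <- tf_post
    out$truth$meth_tumor_level <- tumor_level
    out$truth$meth_true_delta <- out$methylation$true_delta
  }

  if ("survival" %in% components) {
    set.seed(config$seed + 5L)
    deltas <- if (!is.null(out$truth$meth_true_delta)) out$truth$meth_true_delta
    os <- simulate_survival(cluster, deltas,
                            baseline_hazard = config$baseline_hazard,
                            hr_cluster_high = config$hr_cluster_high,
                            hr_large_decrease = config$hr_large_decrease,
                            censoring_rate = config$censoring_rate)
    pfs <- simulate_survival(cluster, deltas,
                             baseline_hazard = config$baseline_hazard * 5 / 3,
                             hr_cluster_high = config$hr_cluster_high,
                             hr_large_decrease = config$hr_large_decrease,
                             censoring_rate = config$censoring_rate)
    out$truth$os_time <- os$time; out$truth$os_event <- os$event
    out$truth$pfs_time <- pfs$time; out$truth$pfs_event <- pfs$event
  }

  structure(out, class = "cfcin_cohort")
}
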