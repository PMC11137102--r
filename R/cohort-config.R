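#' Configuration for the synthetic paired tissue/plasma cohort
#'
#' Bundles every tunable of the cohort generator with validated defaults.
#' The default cohort emulates the study design the pipeline targets: a
#' bevacizumab-treated metastatic colorectal cancer cohort of 74 patients
#' with paired tumor tissue and plasma, a low-CIN cluster-1 prevalence of
#' 0.1, plasma tumor fractions substantially lower than matched tissue
#' (ratio 0.6), low-coverage WGS read counts on a 500 kb bin grid, and
#' methylation target regions that are near-unmethylated (mean beta < 0.03)
#' in healthy plasma and hypermethylated in tumor.
#'
#' @param n_patients Number of patients (each with tissue + plasma).
#' @param cluster_probs Probabilities of CIN clusters 1, 2, 3; must sum to 1.
#' @param tissue_tf_range Range the tissue tumor fraction is drawn from.
#' @param plasma_to_tissue_tf_ratio Plasma tumor fraction as a multiple of
#'   the matched tissue fraction (deterministic scaling).
#' @param cluster1_tf_factor Multiplier on the tissue tumor fraction of
#'   cluster-1 patients; low-CIN tumors shed less tumor DNA, and cluster-1
#'   tumor fractions are markedly lower in the cohorts this emulates.
#' @param bin_size Genomic bin width in bases.
#' @param n_bins Total number of bins across the synthetic genome.
#' @param n_chrom Number of equal-sized synthetic chromosomes.
#' @param reads_per_sample Expected total read count per sample.
#' @param nb_size Negative-binomial dispersion (size) of per-bin counts;
#'   `Inf` gives Poisson sampling.
#' @param n_amp_peaks,n_del_peaks Number of amplification / deletion peak
#'   regions (defaults 43 and 59).
#' @param n_meth_regions Number of targeted methylation regions.
#' @param n_healthy Healthy plasma samples for the coverage reference panel.
#' @param n_healthy_meth Healthy samples in the methylation reference set.
#' @param treatment_effect Mean drop in tumor-component methylation beta for
#'   responders between baseline and on-treatment sampling.
#' @param responder_prob Probability a patient responds (methylation drop).
#' @param meth_noise_sd Bounded noise added to observed betas per
#'   sample x region (binomial sampling at moderate coverage).
#' @param meth_indiv_sd Per-individual baseline methylation offset.
#' @param nf_noise_sd Noise on the nucleosome mixture weight around the
#'   plasma tumor fraction.
#' @param cluster3_nf_het_prob,cluster3_nf_het_factor Cluster-3 nucleosome
#'   heterogeneity: with this probability a cluster-3 sample's mixture
#'   weight is damped by this factor, giving the bimodal low/high score
#'   profile seen for that cluster.
#' @param n_fragments Fragment starts simulated per nucleosome sample.
#' @param baseline_hazard Baseline event hazard per day for overall survival.
#' @param hr_cluster_high Hazard ratio of CIN-high (clusters 2/3) vs cluster 1.
#' @param hr_large_decrease Hazard ratio of the large-methylation-decrease
#'   group vs the rest.
#' @param censoring_rate Target fraction of censored records.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 74,
                          cluster_probs = c(0.1, 0.45, 0.45),
                          tissue_tf_range = c(0.1, 0.5),
                          plasma_to_tissue_tf_ratio = 0.6,
                          cluster1_tf_factor = 0.5,
                          bin_size = 5e5,
                          n_bins = 5600,
                          n_chrom = 14,
                          reads_per_sample = 5.6e6,
                          nb_size = 2000,
                          n_amp_peaks = 43,
                          n_del_peaks = 59,
                          n_meth_regions = 200,
                          n_healthy = 20,
                          n_healthy_meth = 41,
                          treatment_effect = 0.15,
                          responder_prob = 0.5,
                          meth_noise_sd = 0.04,
                          meth_indiv_sd = 0.01,
                          nf_noise_sd = 0.05,
                          cluster3_nf_het_prob = 0.5,
                          cluster3_nf_het_factor = 0.35,
                          n_fragments = 2e4,
                          baseline_hazard = 1 / 500,
                          hr_cluster_high = 0.25,
                          hr_large_decrease = 0.4,
                          censoring_rate = 0.2,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1, length(cluster_probs) == 3)
  if (abs(sum(cluster_probs) - 1) > 1e-12 ||
      any(cluster_probs < 0) || any(cluster_probs > 1))
    stop("cluster_probs must be three probabilities summing to 1")
  if (length(tissue_tf_range) != 2 || any(tissue_tf_range < 0) ||
      any(tissue_tf_range > 1) || diff(tissue_tf_range) < 0)
    stop("tissue_tf_range must be an ordered interval within [0, 1]")
  if (plasma_to_tissue_tf_ratio <= 0)
    stop("plasma_to_tissue_tf_ratio must be positive")
  stopifnot(bin_size > 0, n_bins >= n_chrom, reads_per_sample > 0,
            n_amp_peaks >= 0, n_del_peaks >= 0,
            censoring_rate >= 0, censoring_rate <= 1)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

#' Bin grid of the synthetic genome
#'
#' @param config A [cohort_config()].
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), one row
#'   per bin, chromosomes of equal size.
#' @export
make_bins <- function(config) {
  per_chr <- config$n_bins %/% config$n_chrom
  n_used <- per_chr * config$n_chrom
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), each = per_chr)
  start <- rep(seq_len(per_chr) - 1, config$n_chrom) * config$bin_size
  data.frame(chrom = chrom, start = start, end = start + config$bin_size)[seq_len(n_used), ]
}
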