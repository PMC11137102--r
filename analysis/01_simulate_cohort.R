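#!/usr/bin/env Rscript
# Generate the synthetic paired tissue/plasma cohort and export its ground
# truth and interchange files. The cohort emulates a bevacizumab-treated
# mCRC study: 74 patients, cluster-1 prevalence 0.1, plasma tumor
# fractions 0.6x their matched tissue, paired baseline/on-treatment
# methylation, and survival linked to CIN cluster and methylation response.

source("analysis/00_common.R")

cohort <- get_cohort()
truth <- cohort$truth

msg("cohort: %d patients; cluster sizes %s", nrow(truth),
    paste(table(truth$cluster), collapse = "/"))
msg("tissue tumor fraction: %.2f-%.2f; plasma: %.2f-%.2f",
    min(truth$tf_tissue), max(truth$tf_tissue),
    min(truth$tf_plasma), max(truth$tf_plasma))

write_tsv(truth, file.path(RESULTS_DIR, "ground_truth.tsv"),
          metadata = c(seed = COHORT_SEED))
write_bed(cohort$peaks[, c("chrom", "start", "end", "label", "direction")],
          file.path(RESULTS_DIR, "peaks.bed"))
write_tsv(as.data.frame(t(cohort$centroids)),
          file.path(RESULTS_DIR, "centroids.tsv"))
write_bed(cbind(cohort$nucleosome$track[, "chrom", drop = FALSE],
                start = cohort$nucleosome$track$pos,
                end = cohort$nucleosome$track$pos + 1),
          file.path(RESULTS_DIR, "nucleosome_track.bed"))

# one example plasma coverage profile as a BED-like bin table
ex <- cohort$plasma_profiles[[1]]
write_bed(cbind(ex$bins, count = ex$counts),
          file.path(RESULTS_DIR, "example_plasma_bins.bed"))

msg("ground truth and interchange files written to %s", RESULTS_DIR)
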