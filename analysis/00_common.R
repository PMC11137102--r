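# Shared setup for the analysis scripts: one cohort configuration, one
# seed, one results directory. Each numbered script regenerates what it
# needs from this seed, so the scripts can be run independently and still
# agree with one another.

library(cfcin)

RESULTS_DIR <- "results/analysis"
COHORT_SEED <- 20260924L
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

cohort_cfg <- function() cohort_config(seed = COHORT_SEED)

# cached cohort: simulate once per script run, reuse across sections
get_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_cfg())
    cache
  }
})

msg <- function(...) cat(sprintf(...), "\n")
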