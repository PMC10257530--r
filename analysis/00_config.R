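# Shared settings for the analysis drivers. Every script regenerates its
# inputs from this seed, so each one can be run on its own; all outputs go
# under results/.
suppressMessages({
  library(methylsynergy)
  library(data.table)
})

SEED <- 20260924L
OUT <- "results"
dir.create(OUT, showWarnings = FALSE)

# study-shaped cohort: 4 groups x 3 replicates, bimodal baseline, planted
# hypomethylated regions shared across the treatment arms, and a planted
# drug synergy of 0.15 viability fraction on the plate side
study_truth <- function() simulation_truth(seed = SEED, n_cpgs = 1e5,
                                           epsilon = 0.15)
study_cfg <- analysis_config()   # >=5x, 2-of-3, |diff| >= 35, q < 0.01

unite_all <- function(cohort, cfg = study_cfg) {
  gs <- split(cohort$samples, sub("_[0-9]+$", "", names(cohort$samples)))
  lapply(gs, function(s) unite_groups(s, min_coverage = cfg$min_coverage,
                                      min_per_group = cfg$min_per_group))
}
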