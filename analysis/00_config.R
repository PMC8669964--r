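# Shared settings for the analysis scripts: the synthetic study conditions
# and where stage outputs live. Every script can be rerun independently;
# stages read their inputs from results/study/.

library(panelIFS)

STUDY_SEED <- 20260926
STUDY_DIR <- "results/study"

# 5 unbalanced tumor-type-like classes (200 cell-line-like samples),
# 500 genes: 25 class-informative, 15 redundant copies, 460 noise;
# log2 effect size 2, within-class sd 0.5 (see the methods vignette)
study_spec <- function() {
  synthetic_spec(
    n_classes = 5, class_sizes = c(60, 45, 40, 30, 25),
    n_informative = 25, n_redundant = 15, n_noise = 460,
    effect_size = 2, noise_sd = 0.5, redundancy_sd = 0.25,
    seed = stage_seed(STUDY_SEED, "study"))
}

study_path <- function(...) {
  dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)
  file.path(STUDY_DIR, ...)
}
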