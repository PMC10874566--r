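# Shared settings for the analysis scripts.
#
# The study conditions mirror the acquisition they emulate: 1024 x 1024 um
# frames (1 um/px), 11-plane z-stacks (2 um step over 20 um), 6 slices per
# mouse (2 per anteroposterior subdivision), and the default marker
# colocalization fractions. Cohort sizes for the image-heavy stages are kept
# to a few mice so each script runs in minutes on a laptop; the statistics
# scripts use the full 5 naive + 10 open-field design.

library(clamap)

MASTER_SEED <- 20240201L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

base_generator <- function(seed = MASTER_SEED) generator_config(seed = seed)

msg <- function(...) cat(sprintf(...), "\n")
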