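# Shared settings for the analysis workflow. Each numbered script can be
# run from the repository root with, e.g.:
#   Rscript analysis/01_simulate.R
# Text outputs go to results/, large intermediates to scratch/.

library(pantrio)

SEED <- 20141203L
RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

trio_config <- function() sim_config(seed = SEED)

genome_names <- function() c("A", "B", "C")
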