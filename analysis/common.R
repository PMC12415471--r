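# shared settings for the numbered analysis scripts; source() this first
library(cernaflow)

ANALYSIS_SEED <- 20250331L
RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "sim")

analysis_config <- function() sim_config(seed = ANALYSIS_SEED)

dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
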