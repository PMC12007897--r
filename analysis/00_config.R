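# Shared configuration for the analysis scripts. Every script can be run
# from the repository root as `Rscript analysis/NN_*.R`; stages communicate
# through plain-text files under results/.

suppressPackageStartupMessages(library(airlur))

SEED <- 2016L
YEAR <- 2016L
POLLUTANT <- "pm25"
N_MONITORS <- 150L
N_BLOCKS <- 2000L
SWEEP_GRID <- c(5, 10, 15)
K_PLS <- 2L

RES <- "results"
SIM_DIR <- file.path(RES, "sim")
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)

path_monitors <- file.path(SIM_DIR, "monitors.csv")
path_blocks <- file.path(SIM_DIR, "blocks.csv")
path_landscape <- file.path(SIM_DIR, "landscape")
path_truth_blocks <- file.path(SIM_DIR, "truth_at_blocks.csv")
path_annual <- file.path(RES, "annual.csv")
path_features <- file.path(RES, "features.csv")
path_features_meta <- file.path(RES, "features_meta.json")
path_sweep <- file.path(RES, "cv_sweep.csv")
path_model <- file.path(RES, "model.json")
path_selected <- file.path(RES, "selected_variables.csv")
path_block_pred <- file.path(RES, "block_predictions.csv")
path_level <- function(level) file.path(RES, sprintf("pw_%s_%d_%s.csv",
                                                     level, YEAR, POLLUTANT))
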