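# Stage 3: predictor-variable extraction at the QC-passing monitor sites.
# Road length / source count / areally apportioned population in buffers of
# 100 m to 15 km, plus satellite sample, distance to the nearest source and
# raw position.

source("analysis/00_config.R")

land <- read_landscape(path_landscape)
annual <- read_annual_csv(path_annual)
inc <- annual[annual$qc_status == "included", ]

spec <- default_variable_spec()
fm <- assemble_feature_matrix(land, inc, spec)
write_feature_matrix(fm, path_features, path_features_meta)

message(sprintf("feature matrix: %d sites x %d variables",
                nrow(fm$values), ncol(fm$values)))
rng <- apply(fm$values, 2, function(v) diff(range(v)))
message("non-constant variables: ", sum(rng > 0), " of ", ncol(fm$values))
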