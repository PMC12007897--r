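# Stage 4: model testing. Forward selection inside every training fold,
# PLS (2 components) + universal kriging fit by maximum likelihood, and the
# predictor-count sweep under conventional and spatially clustered 10-fold
# cross-validation; metrics are MSE-R2 and sRMSE over pooled held-out
# predictions on the native scale.

source("analysis/00_config.R")

fm <- read_feature_matrix(path_features, path_features_meta)
annual <- read_annual_csv(path_annual)
inc <- annual[annual$qc_status == "included", ]
stopifnot(identical(fm$site_ids, inc$site_id))
coords <- cbind(inc$x, inc$y)

tab <- sweep_n_predictors(fm, inc$value_native, coords, grid = SWEEP_GRID,
                          k_pls = K_PLS, seed = SEED + 4L)
write.csv(tab, path_sweep, row.names = FALSE)
print(tab, row.names = FALSE)

conv <- tab[tab$scheme == "conventional", ]
best <- conv[which.max(conv$mse_r2), ]
message(sprintf("best conventional-CV model: %d predictors (R2 %.3f, sRMSE %.3f)",
                best$n_predictors, best$mse_r2, best$srmse))
message("conventional vs clustered R2 at that size: ",
        sprintf("%.3f vs %.3f", best$mse_r2,
                tab$mse_r2[tab$scheme == "clustered" &
                             tab$n_predictors == best$n_predictors]))
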