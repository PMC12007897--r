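# Stage 5: final model and application. Forward selection at the sweep's
# best predictor count on all QC-passing sites, PLS-UK fit, prediction at
# every block centroid, and population-weighted aggregation to block group,
# tract and county.

source("analysis/00_config.R")

fm <- read_feature_matrix(path_features, path_features_meta)
annual <- read_annual_csv(path_annual)
inc <- annual[annual$qc_status == "included", ]
coords <- cbind(inc$x, inc$y)
land <- read_landscape(path_landscape)
blocks <- read_blocks_csv(path_blocks)

tab <- read.csv(path_sweep)
conv <- tab[tab$scheme == "conventional", ]
best_n <- conv$n_predictors[which.max(conv$mse_r2)]

sel <- forward_select(fm, inc$value_sqrt, best_n)
write.csv(data.frame(step = seq_along(sel$variables),
                     variable = sel$variables,
                     partial_f = c(NA, sel$partial_f[-1]),
                     sse = sel$sse),
          path_selected, row.names = FALSE)
model <- fit_plsuk(fm$values[, sel$variables, drop = FALSE],
                   inc$value_native, coords, k = K_PLS,
                   pollutant = POLLUTANT, year = YEAR)
plsuk_write_json(model, path_model)
message(sprintf("fitted covariance: nugget %.4f, partial sill %.4f, range %.1f km",
                model$uk$tau2, model$uk$sigma2, model$uk$phi))

spec_sel <- fm$spec[match(sel$variables, fm$spec$name), ]
est <- predict_blocks(model, blocks, land, spec_sel)
write.csv(est, path_block_pred, row.names = FALSE)

truth <- read.csv(path_truth_blocks, colClasses = c(block_fips = "character"))
stopifnot(identical(truth$block_fips, est$block_fips))
message(sprintf("block predictions: MAE vs truth %.3f (truth SD %.3f)",
                mean(abs(est$concentration - truth$truth)), sd(truth$truth)))

for (level in c("block_group", "tract", "county")) {
  agg <- population_weighted_aggregate(est, level)
  write_estimates(agg, POLLUTANT, YEAR, path_level(level))
  message(sprintf("%-11s: %3d geographies, pw mean %.2f",
                  level, nrow(agg),
                  sum(agg$pw_concentration * agg$total_population) /
                    sum(agg$total_population)))
}
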