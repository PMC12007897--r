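# Stage 6: gather the headline numbers of the whole run into one table.

source("analysis/00_config.R")

annual <- read_annual_csv(path_annual)
inc <- annual[annual$qc_status == "included", ]
tab <- read.csv(path_sweep)
conv <- tab[tab$scheme == "conventional", ]
best_i <- which.max(conv$mse_r2)
best_n <- conv$n_predictors[best_i]
clus_at_best <- tab[tab$scheme == "clustered" & tab$n_predictors == best_n, ]
model <- plsuk_read_json(path_model)
county <- read_estimates(path_level("county"))
est <- read.csv(path_block_pred, colClasses = c(block_fips = "character"))
truth <- read.csv(path_truth_blocks, colClasses = c(block_fips = "character"))

summary_tab <- data.frame(
  quantity = c("monitors_included", "qc_pass_fraction", "best_n_predictors",
               "conventional_cv_r2", "conventional_cv_srmse",
               "clustered_cv_r2", "clustered_cv_srmse",
               "fitted_nugget", "fitted_partial_sill", "fitted_range_km",
               "block_mae_vs_truth", "national_pw_concentration"),
  value = c(nrow(inc), nrow(inc) / nrow(annual), best_n,
            conv$mse_r2[best_i], conv$srmse[best_i],
            clus_at_best$mse_r2, clus_at_best$srmse,
            model$uk$tau2, model$uk$sigma2, model$uk$phi,
            mean(abs(est$concentration - truth$truth)),
            sum(county$pw_concentration * county$total_population) /
              sum(county$total_population)))
write.csv(summary_tab, file.path(RES, "summary.csv"), row.names = FALSE)
print(summary_tab, row.names = FALSE, digits = 4)
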