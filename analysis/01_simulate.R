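# Stage 1: build the synthetic study region. A 300-km projected domain with
# four urban foci, roads, point sources, a 2-km population raster and a 25-km
# satellite-proxy raster; a sqrt-scale truth field (linear mean in the
# landscape covariates + exponential-covariance Gaussian random field); one
# year of daily PM2.5 monitor series at urban-clustered sites with structured
# missingness; and census blocks with nested FIPS codes.

source("analysis/00_config.R")

land <- generate_landscape(seed = SEED)
truth <- generate_truth_field(land, seed = SEED + 1L)
series <- sample_monitor_series(truth, n_sites = N_MONITORS, year = YEAR,
                                pollutant = POLLUTANT, missingness = 0.1,
                                clustered = TRUE, seed = SEED + 2L)
blocks <- generate_blocks(N_BLOCKS, land, seed = SEED + 3L)

write_landscape(land, path_landscape)
write_monitor_csv(series, path_monitors)
write_blocks_csv(blocks, path_blocks)
# noise-free truth at block centroids, kept for the final error audit
truth_native <- truth_eval_native(truth, cbind(blocks$x, blocks$y))
write.csv(data.frame(block_fips = blocks$block_fips, truth = truth_native),
          path_truth_blocks, row.names = FALSE)

true_sqrt <- vapply(series, function(s) s$truth_sqrt, 0)
message(sprintf("landscape: %d roads, %d sources, %d foci over %.0f km",
                nrow(land$road_segments), nrow(land$point_sources),
                nrow(land$foci), unname(land$domain_bounds["xmax"])))
message(sprintf("monitors: %d sites, true native concentrations %.1f-%.1f",
                length(series), min(true_sqrt)^2, max(true_sqrt)^2))
message(sprintf("blocks: %d, total population %d, %d counties",
                nrow(blocks), sum(blocks$population),
                length(unique(blocks$county_fips))))
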