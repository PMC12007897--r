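#' Model application: block predictions and population-weighted aggregation
#'
#' The fitted model is applied at census-block centroids with nonzero
#' population; block estimates are then population-weighted averaged to
#' block-group, tract and county geographies, identified by nested FIPS
#' prefixes (kept as zero-padded strings throughout — leading zeros are
#' semantic).
#'
#' @name application
NULL

#' Predict concentrations at block centroids
#'
#' Features are assembled at the centroids with the same variable spec used
#' in training (verified against the model's `variable_names`; a mismatch is
#' an error) and the model applied in batches whose size cannot affect the
#' output, since both feature assembly and kriging prediction are pointwise.
#'
#' @param model a `plsuk`.
#' @param blocks block table from [generate_blocks()] (or
#'   [read_blocks_csv()]), columns x, y (projected km) or lon/lat matching
#'   the model's metric, plus FIPS and population.
#' @param landscape the `landscape` the features come from.
#' @param spec the training variable spec.
#' @param batch_size blocks per evaluation batch.
#' @return data.frame of block estimates: FIPS lineage, lon, lat,
#'   population, concentration (native units, >= 0).
#' @export
predict_blocks <- function(model, blocks, landscape,
                           spec = default_variable_spec(),
                           batch_size = 500) {
  # the model may retain a subset of the spec (constant columns are dropped
  # at fit time), but every training variable must be computable from spec
  if (!all(model$variable_names %in% spec$name))
    stop("variable spec does not match the model's training variables")
  if (any(blocks$population <= 0)) stop("blocks must have population > 0")
  n <- nrow(blocks)
  conc <- numeric(n)
  for (lo in seq(1, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1, n)
    b <- blocks[lo:hi, , drop = FALSE]
    fm <- assemble_feature_matrix(landscape, data.frame(x = b$x, y = b$y),
                                  spec = spec)
    p <- predict(model, fm, cbind(b$x, b$y))
    conc[lo:hi] <- p$pred_native
  }
  data.frame(block_fips = blocks$block_fips, bg_fips = blocks$bg_fips,
             tract_fips = blocks$tract_fips, county_fips = blocks$county_fips,
             lon = blocks$lon, lat = blocks$lat,
             population = blocks$population, concentration = conc,
             stringsAsFactors = FALSE)
}

#' Population-weighted aggregation of block estimates
#'
#' Per geography g: `pw = sum(pop_i * conc_i) / sum(pop_i)` over member
#' blocks i. Weighted means are associative, so aggregating blocks directly
#' to tract equals aggregating block -> block group -> tract with
#' population re-weighting.
#'
#' @param estimates block estimates from [predict_blocks()], or any
#'   data.frame with the FIPS columns, `population` and `concentration`.
#' @param level `"block_group"`, `"tract"` or `"county"`.
#' @return data.frame sorted by FIPS: geography_level, fips,
#'   pw_concentration, total_population, n_blocks.
#' @export
population_weighted_aggregate <- function(estimates,
                                          level = c("block_group", "tract",
                                                    "county")) {
  level <- match.arg(level)
  if (nrow(estimates) == 0) stop("estimates must be non-empty")
  key <- switch(level, block_group = estimates$bg_fips,
                tract = estimates$tract_fips,
                county = estimates$county_fips)
  wt <- if ("total_population" %in% names(estimates))
    estimates$total_population else estimates$population
  conc <- if ("pw_concentration" %in% names(estimates))
    estimates$pw_concentration else estimates$concentration
  nb <- if ("n_blocks" %in% names(estimates)) estimates$n_blocks
        else rep(1L, nrow(estimates))
  pop <- tapply(wt, key, sum)
  if (any(pop <= 0)) stop("zero total population in a geography")
  pw <- tapply(wt * conc, key, sum) / pop
  out <- data.frame(geography_level = level, fips = names(pw),
                    pw_concentration = as.numeric(pw),
                    total_population = as.numeric(pop),
                    n_blocks = as.integer(tapply(nb, key, sum)),
                    stringsAsFactors = FALSE)
  out[order(out$fips), , drop = FALSE]
}

#' Write / read geography estimates as CSV
#'
#' Fixed column order (fips, year, pollutant, pw_concentration,
#' total_population, n_blocks), rows sorted by FIPS, FIPS as zero-padded
#' strings. An empty estimate list produces a header-only file.
#'
#' @param estimates output of [population_weighted_aggregate()].
#' @param pollutant,year metadata columns.
#' @param path file path.
#' @export
write_estimates <- function(estimates, pollutant, year, path) {
  nr <- nrow(estimates)
  df <- data.frame(fips = estimates$fips, year = rep(year, nr),
                   pollutant = rep(pollutant, nr),
                   pw_concentration = estimates$pw_concentration,
                   total_population = estimates$total_population,
                   n_blocks = estimates$n_blocks, stringsAsFactors = FALSE)
  df <- df[order(df$fips), , drop = FALSE]
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = TRUE),
           error = function(e) stop("failed writing ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  utils::read.csv(path, colClasses = c(fips = "character",
                                       pollutant = "character"))
}
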