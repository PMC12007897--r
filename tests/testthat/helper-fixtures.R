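# Shared fixtures: small, cheap objects rebuilt per test file.

tiny_landscape <- function(seed = 101, ...) {
  generate_landscape(seed = seed, n_roads = 25, n_sources = 12,
                     domain_km = 150, n_foci = 3, pop_cell_km = 3,
                     sat_cell_km = 25, ...)
}

tiny_truth <- function(land = tiny_landscape(), seed = 202, ...) {
  generate_truth_field(land, seed = seed, ...)
}

# hand-build a daily monitor series on given day-of-year indices
make_daily_series <- function(days, values = NULL, year = 2016,
                              pollutant = "pm25", site_id = "T001") {
  day1 <- as.Date(sprintf("%d-01-01", year))
  if (is.null(values)) values <- rep(8, length(days))
  structure(list(site_id = site_id, lon = -95, lat = 38, x = 0, y = 0,
                 pollutant = pollutant, cadence = "daily", year = year,
                 schedule_design = NA_character_, truth_sqrt = NA_real_,
                 truth_native = NA_real_,
                 records = data.frame(date = day1 + days - 1,
                                      hour = NA_integer_, value = values)),
            class = "monitor_series")
}

# hand-build an hourly series: `hours_by_day` is a named list
# (day-of-year -> integer hours present), `value_fn(day, hour)` gives values
make_hourly_series <- function(hours_by_day, value_fn = function(d, h) 30,
                               year = 2016, pollutant = "no2",
                               site_id = "T001") {
  day1 <- as.Date(sprintf("%d-01-01", year))
  rows <- lapply(names(hours_by_day), function(d) {
    dd <- as.integer(d)
    h <- hours_by_day[[d]]
    data.frame(date = day1 + dd - 1, hour = h,
               value = vapply(h, function(hh) value_fn(dd, hh), 0))
  })
  structure(list(site_id = site_id, lon = -95, lat = 38, x = 0, y = 0,
                 pollutant = pollutant, cadence = "hourly", year = year,
                 schedule_design = NA_character_, truth_sqrt = NA_real_,
                 truth_native = NA_real_, records = do.call(rbind, rows)),
            class = "monitor_series")
}

# two counties with nested tracts/BGs, hand-set populations/concentrations
make_block_fixture <- function() {
  data.frame(
    block_fips = c("990010001001001", "990010001001002", "990010001002001",
                   "990010002001001", "990020001001001", "990020001001002"),
    bg_fips = c("990010001001", "990010001001", "990010001002",
                "990010002001", "990020001001", "990020001001"),
    tract_fips = c("99001000100", "99001000100", "99001000100",
                   "99001000200", "99002000100", "99002000100"),
    county_fips = c("99001", "99001", "99001", "99001", "99002", "99002"),
    lon = 0, lat = 0,
    population = c(1, 3, 2, 4, 10, 30),
    concentration = c(4, 8, 5, 10, 2, 6),
    stringsAsFactors = FALSE)
}

# simulate directly from the universal-kriging data model:
# y = F beta + GRF(sigma2, phi) + N(0, tau2)
simulate_uk_data <- function(n, beta = c(3, 0.8, -0.5), tau2 = 0.05,
                             sigma2 = 0.2, phi = 20, domain = 100, seed = 1) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, domain), runif(n, 0, domain))
  scores <- cbind(rnorm(n), rnorm(n))
  D <- dist_km(coords)
  Sigma <- sigma2 * exp(-D / phi)
  L <- t(chol(Sigma + diag(1e-10, n)))
  y <- drop(cbind(1, scores) %*% beta) + drop(L %*% rnorm(n)) +
    rnorm(n, 0, sqrt(tau2))
  list(coords = coords, scores = scores, y = y,
       theta = c(tau2, sigma2, phi), beta = beta)
}
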