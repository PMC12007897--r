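#' Synthetic monitor series and census blocks
#'
#' Emulates regulatory air-quality monitoring extracts: hourly series for
#' gases (CO, NO2, SO2, O3), daily for particulate matter, with everyday /
#' 1-in-3 / 1-in-6 reporting schedules, missing-completely-at-random dropout
#' plus an optional contiguous gap per site (so the maximum-gap QC rule has
#' something to reject), and sites optionally clustered around urban foci to
#' contrast conventional with spatially clustered cross-validation.
#'
#' @name synthetic-monitors
NULL

pollutant_cadence <- function(pollutant) {
  switch(tolower(pollutant),
         pm25 = , pm10 = "daily",
         co = , no2 = , so2 = , o3 = "hourly",
         stop("unknown pollutant: ", pollutant))
}

days_in_year <- function(year) {
  as.integer(as.Date(sprintf("%d-12-31", year)) -
               as.Date(sprintf("%d-01-01", year))) + 1L
}

# hour-of-day shape; O3 peaks mid-afternoon and is scaled so the max 8-h
# rolling mean of the profile is 1 (the O3 annual metric is built from daily
# max 8-h values); other gases are scaled to mean 1 (metric = daily mean)
diurnal_profile <- function(pollutant) {
  h <- 0:23
  if (tolower(pollutant) == "o3") {
    p <- 0.35 + exp(-((h - 14.5)^2) / (2 * 3.5^2))
    m8 <- max(vapply(0:16, function(s) mean(p[(s + 1):(s + 8)]), 0))
    p / m8
  } else {
    p <- 1 + 0.3 * sin(2 * pi * (h - 9) / 24)
    p / mean(p)
  }
}

#' Sample synthetic monitor series from a truth field
#'
#' Each site receives a true annual sqrt-scale value (smooth field + nugget
#' noise) and a daily/hourly series whose annual QC metric is centred on the
#' corresponding native-scale truth, modulated by a seasonal cycle,
#' multiplicative lognormal day-to-day noise and (for gases) a diurnal
#' profile.
#'
#' @param truth a `truth_field`.
#' @param n_sites number of monitoring sites (>= 2; kriging is undefined
#'   below that).
#' @param year calendar year of the series.
#' @param pollutant one of pm25, pm10, co, no2, so2, o3 (sets the cadence).
#' @param schedule_mix named proportions over `everyday`, `one_in_three`,
#'   `one_in_six`; must sum to 1. Default: all-everyday for hourly gases,
#'   a 50/35/15 mix for particulate monitors.
#' @param missingness MCAR dropout rate on scheduled reporting days, in [0,1).
#' @param clustered if TRUE, sites are drawn around the urban foci (with a
#'   small uniform background); if FALSE, uniformly over the domain.
#' @param seed integer seed.
#' @param gap_prob probability a site receives one contiguous reporting gap.
#' @param gap_len_range min/max gap length in days.
#' @param hour_missingness MCAR dropout rate on individual hours (hourly
#'   cadence only); drives the 18-h daily-validity rule.
#' @param temporal_cv day-to-day coefficient of variation.
#' @return list of `monitor_series` objects. Each carries its true sqrt-scale
#'   annual value in `truth_sqrt` for simulation studies.
#' @export
sample_monitor_series <- function(truth, n_sites, year = 2016,
                                  pollutant = "pm25",
                                  schedule_mix = NULL,
                                  missingness = 0.1, clustered = FALSE,
                                  seed = 1, gap_prob = 0.15,
                                  gap_len_range = c(20, 60),
                                  hour_missingness = 0.04,
                                  temporal_cv = 0.25) {
  if (n_sites < 2) stop("n_sites must be >= 2 (kriging undefined for fewer)")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  cadence <- pollutant_cadence(pollutant)
  if (is.null(schedule_mix)) {
    schedule_mix <- if (cadence == "hourly") c(everyday = 1) else
      c(everyday = 0.5, one_in_three = 0.35, one_in_six = 0.15)
  }
  if (abs(sum(schedule_mix) - 1) > 1e-8) stop("schedule_mix must sum to 1")
  land <- truth$landscape
  L <- unname(land$domain_bounds["xmax"])
  ndays <- days_in_year(year)
  day1 <- as.Date(sprintf("%d-01-01", year))
  prof <- diurnal_profile(pollutant)
  s_ln <- sqrt(log(1 + temporal_cv^2))

  with_seed(seed, {
    if (clustered) {
      fi <- sample.int(nrow(land$foci), n_sites, replace = TRUE,
                       prob = land$foci$weight)
      bg <- runif(n_sites) < 0.1
      x <- ifelse(bg, runif(n_sites, 0, L), land$foci$x[fi] + rnorm(n_sites, 0, 10))
      y <- ifelse(bg, runif(n_sites, 0, L), land$foci$y[fi] + rnorm(n_sites, 0, 10))
      x <- pmin(pmax(x, 0.01 * L), 0.99 * L)
      y <- pmin(pmax(y, 0.01 * L), 0.99 * L)
    } else {
      x <- runif(n_sites, 0, L); y <- runif(n_sites, 0, L)
    }
    coords <- cbind(x, y)
    a <- truth_eval(truth, coords) + rnorm(n_sites, 0, sqrt(truth$nugget))
    c_native <- back_transform(a)
    scheds <- sample(names(schedule_mix), n_sites, replace = TRUE,
                     prob = schedule_mix)
    ll <- km_to_lonlat(coords)

    lapply(seq_len(n_sites), function(i) {
      sched_days <- switch(scheds[i],
        everyday = seq_len(ndays),
        one_in_three = seq(sample.int(3, 1), ndays, by = 3),
        one_in_six = seq(sample.int(6, 1), ndays, by = 6),
        stop("unknown schedule: ", scheds[i]))
      keep <- sched_days[runif(length(sched_days)) >= missingness]
      if (runif(1) < gap_prob && length(keep) > 0) {
        glen <- sample(seq(gap_len_range[1], gap_len_range[2]), 1)
        gstart <- sample.int(max(ndays - glen, 1), 1)
        keep <- keep[keep < gstart | keep > gstart + glen - 1]
      }
      season <- 1 + 0.2 * cos(2 * pi * (keep - 15) / ndays)
      daily <- c_native[i] * season * exp(rnorm(length(keep), 0, s_ln) - s_ln^2 / 2)
      if (cadence == "daily") {
        rec <- data.frame(date = day1 + keep - 1, hour = NA_integer_,
                          value = pmax(daily, 0))
      } else {
        nh <- length(keep) * 24
        hrs <- rep(0:23, times = length(keep))
        vals <- rep(daily, each = 24) * prof[hrs + 1] *
          exp(rnorm(nh, 0, 0.15) - 0.15^2 / 2)
        ok <- runif(nh) >= hour_missingness
        rec <- data.frame(date = rep(day1 + keep - 1, each = 24)[ok],
                          hour = hrs[ok], value = pmax(vals[ok], 0))
      }
      structure(list(site_id = sprintf("S%04d", i),
                     lon = ll[i, "lon"], lat = ll[i, "lat"],
                     x = coords[i, 1], y = coords[i, 2],
                     pollutant = tolower(pollutant), cadence = cadence,
                     year = year, schedule_design = scheds[i],
                     truth_sqrt = a[i], truth_native = c_native[i],
                     records = rec),
                class = "monitor_series")
    })
  })
}

#' Generate synthetic census blocks with nested FIPS lineage
#'
#' Block centroids follow the population structure (80% around urban foci,
#' 20% uniform background); populations are skewed lognormal, always > 0.
#' FIPS codes are built by prefix so block -> block group -> tract -> county
#' nesting is consistent by construction, mirroring census geography: county
#' (5 digits), tract (11), block group (12), block (15).
#'
#' @param n_blocks number of blocks (>= 1).
#' @param landscape a `landscape`.
#' @param seed integer seed.
#' @return data.frame: block_fips, bg_fips, tract_fips, county_fips, lon,
#'   lat, x, y, population. FIPS columns are character (leading zeros are
#'   semantic).
#' @export
generate_blocks <- function(n_blocks, landscape, seed = 1) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  L <- unname(landscape$domain_bounds["xmax"])
  foci <- landscape$foci
  with_seed(seed, {
    bg_share <- runif(n_blocks) < 0.2
    fi <- sample.int(nrow(foci), n_blocks, replace = TRUE, prob = foci$weight)
    x <- ifelse(bg_share, runif(n_blocks, 0, L), foci$x[fi] + rnorm(n_blocks, 0, 10))
    y <- ifelse(bg_share, runif(n_blocks, 0, L), foci$y[fi] + rnorm(n_blocks, 0, 10))
    x <- pmin(pmax(x, 1e-6), L * (1 - 1e-9))
    y <- pmin(pmax(y, 1e-6), L * (1 - 1e-9))
    pop <- pmax(1, round(rlnorm(n_blocks, log(30), 1.1)))

    # spatial FIPS hierarchy: 3x3 counties, 4x4 tracts per county,
    # 2x2 block groups per tract
    cell <- function(v, nsplit, lo, hi) pmin(floor((v - lo) / (hi - lo) * nsplit), nsplit - 1)
    ci <- cell(x, 3, 0, L); cj <- cell(y, 3, 0, L)
    county_id <- ci * 3 + cj + 1
    cw <- L / 3
    ti <- cell(x - ci * cw, 4, 0, cw); tj <- cell(y - cj * cw, 4, 0, cw)
    tract_id <- ti * 4 + tj + 1
    tw <- cw / 4
    bi <- cell(x - ci * cw - ti * tw, 2, 0, tw)
    bj <- cell(y - cj * cw - tj * tw, 2, 0, tw)
    bg_digit <- bi * 2 + bj + 1
    county_fips <- sprintf("99%03d", county_id)
    tract_fips <- sprintf("%s%06d", county_fips, tract_id * 100)
    bg_fips <- sprintf("%s%d", tract_fips, bg_digit)
    serial <- stats::ave(seq_len(n_blocks), bg_fips, FUN = seq_along)
    if (any(serial > 999)) stop("more than 999 blocks in one block group")
    block_fips <- sprintf("%s%03d", bg_fips, serial)
    ll <- km_to_lonlat(cbind(x, y))
    data.frame(block_fips, bg_fips, tract_fips, county_fips,
               lon = ll[, "lon"], lat = ll[, "lat"], x = x, y = y,
               population = pop, stringsAsFactors = FALSE)
  })
}
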