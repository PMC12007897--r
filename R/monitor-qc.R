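#' Monitor completeness QC and annual metrics
#'
#' Raw regulatory series (hourly for gases, daily for particulate matter) are
#' reduced to annual observations under completeness criteria: a day is valid
#' when it has at least 18 valid hourly measurements; a year is included with
#' at least 244 valid days (everyday schedule), 61 (1-in-3) or 41 (1-in-6);
#' and no more than 45 consecutive days may pass without any measurement.
#' Ozone uses a seasonal metric instead: the mean over May-September of the
#' daily maximum 8-h rolling average, requiring valid days on at least 75% of
#' the 153-day season. Annual values are square-root transformed for
#' modelling, where the sqrt scale makes the Gaussian assumption tenable.
#'
#' Rejections are typed results (status + reason), never errors: a QC run over
#' a network must report which rule failed where.
#'
#' @name monitor-qc
NULL

#' Valid-day thresholds per reporting schedule
#' @export
qc_day_thresholds <- c(everyday = 244L, one_in_three = 61L, one_in_six = 41L)

#' Daily validity and summary for one day of hourly values
#'
#' A day is valid with >= 18 non-missing hours. The summary is the mean of
#' present hours, or for O3 the maximum 8-h rolling average (see
#' [daily_max8()]). Invalid days yield an NA summary, not an error.
#'
#' @param values numeric vector of <= 24 hourly values, NA = missing. If
#'   `hours` is given, values are placed at those hours (0-23).
#' @param hours optional integer hour-of-day labels for `values`.
#' @param pollutant pollutant code; `"o3"` switches to the max 8-h summary.
#' @param min_hours_day validity threshold (default 18).
#' @param min_hours_window hours required in an 8-h window for its mean
#'   (default 6, a common regulatory convention).
#' @return list(valid = logical, summary = numeric or NA).
#' @export
daily_validity <- function(values, hours = NULL, pollutant = "pm25",
                           min_hours_day = 18L, min_hours_window = 6L) {
  if (!is.null(hours)) {
    v <- rep(NA_real_, 24)
    v[hours + 1] <- values
    values <- v
  }
  if (length(values) > 24) stop("a day has at most 24 hourly values")
  n_ok <- sum(!is.na(values))
  if (n_ok < min_hours_day) return(list(valid = FALSE, summary = NA_real_))
  s <- if (tolower(pollutant) == "o3") {
    if (length(values) < 24) values <- c(values, rep(NA_real_, 24 - length(values)))
    daily_max8(values, min_hours_window)
  } else {
    mean(values, na.rm = TRUE)
  }
  list(valid = TRUE, summary = s)
}

#' Daily maximum 8-hour rolling average
#'
#' All 17 windows starting at hours 0-16 are scanned; a window's mean is
#' computed when at least `min_hours_window` of its 8 hours are present.
#'
#' @param values length-24 numeric, NA = missing hour.
#' @param min_hours_window minimum present hours per window (default 6).
#' @return the maximum computable window mean, or NA if none is computable.
#' @export
daily_max8 <- function(values, min_hours_window = 6L) {
  stopifnot(length(values) == 24)
  best <- NA_real_
  for (s in 0:16) {
    w <- values[(s + 1):(s + 8)]
    if (sum(!is.na(w)) >= min_hours_window) {
      m <- mean(w, na.rm = TRUE)
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

#' Classify the reporting schedule of a series
#'
#' By the modal gap (in days) between consecutive reported days: 1 =
#' everyday, 3 = 1-in-3, 6 = 1-in-6. Other modal gaps map to the nearest of
#' the three; exact ties resolve toward the denser schedule, whose stricter
#' valid-day threshold is the conservative choice.
#'
#' @param series a `monitor_series`.
#' @return `"everyday"`, `"one_in_three"` or `"one_in_six"`.
#' @export
classify_schedule <- function(series) {
  days <- sort(unique(series$records$date))
  if (length(days) < 2) stop("schedule unclassifiable: fewer than 2 reported days")
  gaps <- as.integer(diff(days))
  tab <- table(gaps)
  # modal gap; ties between gap values resolve to the smaller gap
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  ref <- c(1L, 3L, 6L)
  names(ref) <- c("everyday", "one_in_three", "one_in_six")
  names(ref)[which.min(abs(ref - modal))]
}

# longest run of consecutive calendar days without any measurement,
# bounded by the calendar year (leading/trailing silence counts)
longest_gap_days <- function(dates, year) {
  days <- sort(unique(as.integer(dates - as.Date(sprintf("%d-01-01", year))))) + 1L
  nd <- days_in_year(year)
  bounds <- c(0L, days, nd + 1L)
  max(diff(bounds) - 1L)
}

qc_result <- function(included, reason, obs = NULL) {
  structure(list(included = included, reason = reason, observation = obs),
            class = "qc_result")
}

# reduce an hourly series to per-day validity/summary
collapse_hourly <- function(series, min_hours_day = 18L, min_hours_window = 6L) {
  rec <- series$records
  split_idx <- split(seq_len(nrow(rec)), rec$date)
  dates <- as.Date(names(split_idx))
  valid <- logical(length(split_idx))
  summ <- rep(NA_real_, length(split_idx))
  for (k in seq_along(split_idx)) {
    idx <- split_idx[[k]]
    dv <- daily_validity(rec$value[idx], hours = rec$hour[idx],
                         pollutant = series$pollutant,
                         min_hours_day = min_hours_day,
                         min_hours_window = min_hours_window)
    valid[k] <- dv$valid; summ[k] <- dv$summary
  }
  data.frame(date = dates, valid = valid, summary = summ)
}

make_annual_obs <- function(series, value_native, n_valid, schedule) {
  list(site_id = series$site_id, lon = series$lon, lat = series$lat,
       x = series$x, y = series$y, pollutant = series$pollutant,
       year = series$year, value_native = value_native,
       value_sqrt = sqrt_transform(value_native),
       n_valid_days = n_valid, schedule = schedule)
}

#' Annual average for non-ozone pollutants, with completeness QC
#'
#' Valid days: for hourly series, days with >= 18 valid hours (summary = mean
#' of present hours); daily PM records count as valid by presence. Included
#' when the valid-day count meets the schedule's threshold (244 / 61 / 41 for
#' everyday / 1-in-3 / 1-in-6, used unchanged in leap years) AND the longest
#' measurement-free run — measured on reported days, including year-edge
#' silence — is at most 45 days. The annual value is the mean of valid-day
#' summaries.
#'
#' @param series a `monitor_series` with pollutant != o3, one calendar year.
#' @param max_gap_days maximum tolerated measurement-free run (default 45).
#' @param min_hours_day daily-validity threshold for hourly cadence.
#' @return a `qc_result`: `included` flag, `reason`
#'   ("ok" | "too_few_reported_days" | "completeness" | "max_gap"), and the
#'   annual observation when included.
#' @export
annual_average <- function(series, max_gap_days = 45L, min_hours_day = 18L) {
  if (tolower(series$pollutant) == "o3")
    stop("use o3_season_metric() for ozone")
  rec <- series$records
  if (length(unique(rec$date)) < 2)
    return(qc_result(FALSE, "too_few_reported_days"))
  schedule <- classify_schedule(series)
  if (series$cadence == "hourly") {
    day <- collapse_hourly(series, min_hours_day = min_hours_day)
  } else {
    agg <- tapply(rec$value, rec$date, mean)
    day <- data.frame(date = as.Date(names(agg)), valid = TRUE,
                      summary = as.numeric(agg))
  }
  n_valid <- sum(day$valid)
  gap <- longest_gap_days(rec$date, series$year)
  if (n_valid < qc_day_thresholds[[schedule]])
    return(qc_result(FALSE, "completeness"))
  if (gap > max_gap_days)
    return(qc_result(FALSE, "max_gap"))
  value <- mean(day$summary[day$valid])
  qc_result(TRUE, "ok", make_annual_obs(series, value, n_valid, schedule))
}

#' Seasonal daily-max-8-h metric for ozone, with completeness QC
#'
#' For each day of the May 1 - September 30 season, the maximum over all 17
#' within-day 8-h rolling means is computed; a day is valid with >= 18 valid
#' hours. The annual metric is the mean of valid-day maxima, included when
#' valid days cover at least 75% of the 153-day season (>= 115 after taking
#' the ceiling).
#'
#' @param series a `monitor_series` with pollutant o3, hourly cadence.
#' @param min_frac required fraction of the season with valid days.
#' @inheritParams annual_average
#' @return a `qc_result` as for [annual_average()].
#' @export
o3_season_metric <- function(series, min_frac = 0.75, min_hours_day = 18L) {
  if (tolower(series$pollutant) != "o3") stop("pollutant must be o3")
  if (series$cadence != "hourly") stop("o3 series must be hourly")
  y <- series$year
  lo <- as.Date(sprintf("%d-05-01", y)); hi <- as.Date(sprintf("%d-09-30", y))
  season_len <- as.integer(hi - lo) + 1L
  rec <- series$records[series$records$date >= lo & series$records$date <= hi, ]
  sseries <- series; sseries$records <- rec
  if (nrow(rec) == 0) return(qc_result(FALSE, "completeness"))
  day <- collapse_hourly(sseries, min_hours_day = min_hours_day)
  ok <- day$valid & !is.na(day$summary)
  n_valid <- sum(ok)
  if (n_valid < ceiling(min_frac * season_len))
    return(qc_result(FALSE, "completeness"))
  value <- mean(day$summary[ok])
  qc_result(TRUE, "ok", make_annual_obs(series, value, n_valid,
                                        classify_schedule(series)))
}

#' Square-root transform and its clamped inverse
#'
#' Forward: sqrt(x), defined for x >= 0. Back: negative sqrt-scale values
#' (which kriging can produce) clamp to 0 before squaring, so native-scale
#' concentrations are never negative.
#'
#' @param value_native non-negative native-scale concentration(s).
#' @return transformed values.
#' @export
sqrt_transform <- function(value_native) {
  if (any(value_native < 0, na.rm = TRUE))
    stop("sqrt_transform requires non-negative input")
  sqrt(value_native)
}

#' @rdname sqrt_transform
#' @param value_sqrt sqrt-scale value(s), any real.
#' @export
back_transform <- function(value_sqrt) pmax(value_sqrt, 0)^2

#' Run QC over a set of monitor series
#'
#' Applies [o3_season_metric()] or [annual_average()] per series and returns
#' one row per site with the QC outcome.
#'
#' @param series_list list of `monitor_series`.
#' @param ... passed to the per-series QC function.
#' @return data.frame: site_id, lon, lat, x, y, pollutant, year,
#'   value_native, value_sqrt, n_valid_days, schedule, qc_status, qc_reason.
#'   Value columns are NA for rejected sites.
#' @export
qc_annual <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    r <- tryCatch(
      if (tolower(s$pollutant) == "o3") o3_season_metric(s, ...)
      else annual_average(s, ...),
      error = function(e) qc_result(FALSE, conditionMessage(e)))
    o <- r$observation
    data.frame(
      site_id = s$site_id, lon = s$lon, lat = s$lat, x = s$x, y = s$y,
      pollutant = s$pollutant, year = s$year,
      value_native = if (r$included) o$value_native else NA_real_,
      value_sqrt = if (r$included) o$value_sqrt else NA_real_,
      n_valid_days = if (r$included) o$n_valid_days else NA_integer_,
      schedule = if (r$included) o$schedule else NA_character_,
      qc_status = if (r$included) "included" else "rejected",
      qc_reason = r$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
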