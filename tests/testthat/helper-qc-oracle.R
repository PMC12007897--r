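# Independent brute-force recount of the monitor completeness rules, used to
# cross-check the package's QC decisions. Deliberately naive: per-day hour
# tallies, a day-by-day scan for the longest gap, and an explicit modal-gap
# classifier. Shares no code with the package implementation.

oracle_qc_decision <- function(series, max_gap = 45) {
  rec <- series$records
  nd <- as.integer(as.Date(sprintf("%d-12-31", series$year)) -
                     as.Date(sprintf("%d-01-01", series$year))) + 1L
  doy <- as.integer(rec$date - as.Date(sprintf("%d-01-01", series$year))) + 1L
  reported <- sort(unique(doy))
  if (length(reported) < 2) return(list(included = FALSE, reason = "too_few"))

  # schedule by modal day gap, nearest of 1/3/6, ties to the denser schedule
  gaps <- diff(reported)
  tab <- sort(table(gaps), decreasing = TRUE)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  dists <- abs(c(1, 3, 6) - modal)
  sched <- c("everyday", "one_in_three", "one_in_six")[which(dists == min(dists))[1]]
  thr <- c(everyday = 244, one_in_three = 61, one_in_six = 41)[[sched]]

  # valid days
  if (series$cadence == "daily") {
    n_valid <- length(reported)
  } else {
    n_valid <- 0
    for (d in reported) {
      hrs <- rec$hour[doy == d]
      if (length(unique(hrs)) >= 18) n_valid <- n_valid + 1
    }
  }

  # longest run of days with no measurement at all, edges included
  has <- rep(FALSE, nd)
  has[reported] <- TRUE
  longest <- run <- 0
  for (d in seq_len(nd)) {
    if (!has[d]) { run <- run + 1; longest <- max(longest, run) }
    else run <- 0
  }

  if (n_valid < thr) return(list(included = FALSE, reason = "completeness"))
  if (longest > max_gap) return(list(included = FALSE, reason = "max_gap"))
  list(included = TRUE, reason = "ok")
}
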