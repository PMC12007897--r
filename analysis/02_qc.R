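# Stage 2: completeness QC. Daily validity (18-h rule for hourly series),
# schedule classification by modal reporting gap, the 244/61/41 valid-day
# thresholds, the 45-day maximum-gap rule, and the square-root transform of
# the annual metric.

source("analysis/00_config.R")

series <- read_monitor_csv(path_monitors, year = YEAR)
annual <- qc_annual(series)
write_annual_csv(annual, path_annual)

message(sprintf("QC: %d of %d monitors included",
                sum(annual$qc_status == "included"), nrow(annual)))
print(table(annual$qc_reason))
inc <- annual[annual$qc_status == "included", ]
message(sprintf("annual means: %.2f-%.2f native, schedules: %s",
                min(inc$value_native), max(inc$value_native),
                paste(names(table(inc$schedule)), table(inc$schedule),
                      sep = "=", collapse = ", ")))
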