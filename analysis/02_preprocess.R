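#!/usr/bin/env Rscript
# Clean the minute-level cohort: dedupe, drop low-MET (device off/charging)
# samples, apply the per-participant 0.05/0.95 temperature quantile band,
# annotate sleep/wake from the nightly summaries, and apply the 70%
# average-daily-completeness filter. Writes the cleaned stream, the
# drop-reason audit and the retained-participant list under results/.

suppressPackageStartupMessages({
  library(thermovar)
  library(data.table)
})

minute <- fread("results/data/minute/nightly.csv")  # nightly summaries
raw <- rbindlist(lapply(list.files("results/data/minute/minute",
                                   full.names = TRUE), fread))
raw[, timestamp := as.POSIXct(timestamp, tz = "UTC")]
minute[, `:=`(date = as.Date(date),
              sleep_start = as.POSIXct(sleep_start, tz = "UTC"),
              sleep_end = as.POSIXct(sleep_end, tz = "UTC"))]

nights <- select_nightly_rows(minute)
clean <- preprocess_series(raw, nights)
kept <- completeness_filter(clean, sample_minutes = 5, required_months = NA)

audit <- dropped_samples(clean)[, .N, by = "reason"]
message(sprintf("input %d samples; retained %d; dropped %d (%s)",
                nrow(raw), nrow(clean$data), nrow(dropped_samples(clean)),
                paste(sprintf("%s=%d", audit$reason, audit$N), collapse = ", ")))
message(sprintf("completeness filter retains %d of %d participants",
                length(kept), length(unique(raw$pid))))

dir.create("results", showWarnings = FALSE)
fwrite(clean$data[pid %in% kept], "results/clean_minute.csv")
fwrite(dropped_samples(clean), "results/drop_audit.csv")
writeLines(kept, "results/retained_pids.txt")
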