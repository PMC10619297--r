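# Cleaning of raw minute-level streams, sleep/wake annotation from nightly
# summaries, and cohort-level completeness filtering.

# A clean_series is the running result of the preprocessing chain: the
# retained samples plus an audit table of dropped samples, each carrying
# exactly one drop reason.
new_clean_series <- function(data, dropped = NULL) {
  empty <- data.table::data.table(pid = character(), timestamp = data$timestamp[0],
                                  reason = character())
  structure(list(data = data, dropped = dropped %||% empty),
            class = "clean_series")
}

as_clean <- function(x) {
  if (inherits(x, "clean_series")) return(x)
  new_clean_series(data.table::as.data.table(x))
}

#' @export
print.clean_series <- function(x, ...) {
  cat(sprintf("<clean_series> %d samples retained, %d dropped\n",
              nrow(x$data), nrow(x$dropped)))
  if (nrow(x$dropped))
    print(x$dropped[, .N, by = "reason"])
  invisible(x)
}

#' Audit table of dropped samples
#'
#' @param x A `clean_series`.
#' @return data.table with columns pid, timestamp, reason.
#' @export
dropped_samples <- function(x) {
  stopifnot(inherits(x, "clean_series"))
  x$dropped
}

record_drops <- function(cs, dt, keep, reason) {
  if (!all(keep)) {
    d <- dt[!keep, c("pid", "timestamp")]
    d[, reason := reason]
    cs$dropped <- data.table::rbindlist(list(cs$dropped, d))
  }
  cs$data <- dt[keep]
  cs
}

#' Sort by local time and remove duplicate time points
#'
#' Establishes a strictly increasing local-time index per participant.
#' Duplicate timestamps are resolved by keeping the first occurrence in
#' input order; dropped samples are flagged `duplicate`.
#'
#' @param raw Minute-level data (data.frame with pid, timestamp,
#'   temperature, met, ...) or a `clean_series`.
#' @return A `clean_series`.
#' @export
index_and_dedupe <- function(raw) {
  cs <- as_clean(raw)
  dt <- cs$data
  if (nrow(dt) == 0L) stop("empty series: no samples to index", call. = FALSE)
  dt <- data.table::copy(dt)
  dt[, .orig := .I]
  data.table::setorderv(dt, c("pid", "timestamp", ".orig"))
  keep <- !duplicated(dt[, c("pid", "timestamp")])
  cs <- record_drops(cs, dt, keep, "duplicate")
  cs$data[, .orig := NULL]
  cs
}

#' Per-participant temperature quantile filter
#'
#' Drops samples whose temperature lies strictly below the participant's
#' `q_low` quantile or strictly above the `q_high` quantile (quantiles by
#' linear interpolation on sorted values, [stats::quantile()] type 7).
#' Dropped samples are flagged `quantile`. The fitted band is stored on the
#' returned `clean_series` and reused on re-application, so the filter (and
#' the full preprocessing chain) is idempotent: the band is a
#' participant-level parameter estimated once, not re-estimated from its
#' own output.
#'
#' @param s Minute-level data or `clean_series`.
#' @param q_low,q_high Quantile bounds, `0 <= q_low < q_high <= 1`.
#' @return A `clean_series` with a per-participant `bands` table.
#' @export
quantile_filter <- function(s, q_low = 0.05, q_high = 0.95) {
  if (!is.numeric(q_low) || !is.numeric(q_high) || q_low < 0 || q_high > 1 ||
      q_low >= q_high)
    stop_config("q_low/q_high", "must satisfy 0 <= q_low < q_high <= 1")
  cs <- as_clean(s)
  dt <- cs$data
  bounds <- cs$bands %||% dt[, {
    qs <- stats::quantile(temperature, c(q_low, q_high), type = 7, names = FALSE)
    list(lo = qs[1], hi = qs[2])
  }, by = "pid"]
  dtb <- bounds[dt, on = "pid"]
  keep <- dtb$temperature >= dtb$lo & dtb$temperature <= dtb$hi
  cs <- record_drops(cs, dt, keep, "quantile")
  cs$bands <- bounds
  cs
}

#' Drop low-MET (device off / charging) samples
#'
#' Samples whose MET reading is strictly below `met_threshold` are dropped
#' and flagged `met_artifact`; a reading exactly at the threshold is
#' retained.
#'
#' @param s Minute-level data or `clean_series`.
#' @param met_threshold MET cutoff (default 0.5).
#' @return A `clean_series`.
#' @export
met_artifact_filter <- function(s, met_threshold = 0.5) {
  cs <- as_clean(s)
  dt <- cs$data
  if (!"met" %in% names(dt))
    stop("schema error: 'met' column is required", call. = FALSE)
  keep <- dt$met >= met_threshold
  record_drops(cs, dt, keep, "met_artifact")
}

#' Select one nightly summary row per participant-night
#'
#' Where a date has several candidate rows, the row with the longest sleep
#' duration wins; ties are broken by the earliest sleep start.
#'
#' @param summaries data.frame with pid, date, sleep_start, sleep_end,
#'   sleep_duration (minutes) and aggregate columns.
#' @return data.table with exactly one row per (pid, date).
#' @export
select_nightly_rows <- function(summaries) {
  dt <- data.table::as.data.table(summaries)
  stopifnot(all(c("pid", "date", "sleep_duration") %in% names(dt)))
  data.table::setorderv(dt, c("pid", "date", "sleep_duration", "sleep_start"),
                        order = c(1L, 1L, -1L, 1L))
  dt[!duplicated(dt[, c("pid", "date")])]
}

#' Annotate samples as asleep or awake from nightly summaries
#'
#' A sample inside a nightly sleep window `[sleep_start, sleep_end)` is
#' labelled `sleep` (half-open, so adjacent windows partition time); other
#' samples on dates covered by a summary are `wake`; samples on dates with
#' no summary (nor one the evening before) are `unknown`.
#'
#' @param s Minute-level data or `clean_series`.
#' @param nights Nightly summaries (one row per pid and date, see
#'   [select_nightly_rows()]).
#' @return A `clean_series` whose data gains/overwrites a `state` column.
#' @export
annotate_sleep_wake <- function(s, nights) {
  cs <- as_clean(s)
  dt <- data.table::copy(cs$data)
  nt <- data.table::as.data.table(nights)
  data.table::setorderv(nt, c("pid", "sleep_start"))
  bad <- nt[, any(sleep_start[-1] < sleep_end[-.N]), by = "pid"]$V1
  if (any(bad))
    stop("validation error: overlapping sleep windows", call. = FALSE)
  dt[, state := "unknown"]
  covered <- unique(nt[, c("pid", "date")])
  dt[, .date := as.Date(timestamp, tz = "UTC")]
  dt[covered, state := "wake", on = c("pid", ".date==date")]
  # morning samples fall on the day after the summary's date
  dt[covered[, list(pid, date = date + 1L)], state := "wake",
     on = c("pid", ".date==date")]
  # interval join for the sleep windows
  dt[, `:=`(.s = timestamp, .e = timestamp)]
  nt[, `:=`(.s = sleep_start, .e = sleep_end)]
  hit <- data.table::foverlaps(dt[, list(pid, .s, .e, .row = .I)],
                               data.table::setkeyv(nt[, list(pid, .s, .e)],
                                                   c("pid", ".s", ".e")),
                               type = "within", nomatch = NULL,
                               by.x = c("pid", ".s", ".e"))
  # foverlaps treats intervals as closed; enforce the half-open convention
  inside <- hit$i..s >= hit$.s & hit$i..s < hit$.e
  dt[hit$.row[inside], state := "sleep"]
  dt[, c(".date", ".s", ".e") := NULL]
  cs$data <- dt
  cs
}

#' Cohort completeness filter
#'
#' Retains participants whose average daily completeness -- the mean over
#' calendar days in the observation span of (observed samples / expected
#' samples per day) -- is at least `threshold`, and (optionally) who have
#' data in every required month.
#'
#' @param minute Minute-level cohort data (pid, timestamp, ...); retained or
#'   raw.
#' @param sample_minutes Sampling interval, to fix the per-day denominator
#'   (1440 / `sample_minutes`).
#' @param threshold Minimum average daily completeness (default 0.70).
#' @param required_months Character vector of months (`"YYYY-MM"`) in which
#'   every retained participant must have data; `NULL` derives it from the
#'   cohort-wide date span; `NA` disables the month rule.
#' @return Character vector of retained pids.
#' @export
completeness_filter <- function(minute, sample_minutes, threshold = 0.70,
                                required_months = NULL) {
  dt <- if (inherits(minute, "clean_series")) minute$data
        else data.table::as.data.table(minute)
  expected <- 1440 / sample_minutes
  dt <- dt[, list(pid, .date = as.Date(timestamp, tz = "UTC"))]
  if (is.null(required_months)) {
    span <- seq(min(dt$.date), max(dt$.date), by = "1 day")
    required_months <- unique(format(span, "%Y-%m"))
  }
  per <- dt[, {
    days <- seq(min(.date), max(.date), by = "1 day")
    obs <- tabulate(match(.date, days), nbins = length(days))
    months <- unique(format(.date, "%Y-%m"))
    list(completeness = mean(pmin(obs / expected, 1)),
         all_months = if (anyNA(required_months)) TRUE
                      else all(required_months %in% months))
  }, by = "pid"]
  per[completeness >= threshold & all_months, pid]
}

#' Full preprocessing chain for minute-level data
#'
#' Dedupe and index, drop low-MET artifacts, apply the per-participant
#' quantile band (computed on MET-cleaned data so charging spikes cannot
#' distort it), then annotate sleep/wake if nightly summaries are given.
#'
#' @param raw Minute-level cohort data.
#' @param nights Optional nightly summaries for annotation.
#' @param q_low,q_high Quantile band (see [quantile_filter()]).
#' @param met_threshold MET cutoff (see [met_artifact_filter()]).
#' @return A `clean_series`.
#' @export
preprocess_series <- function(raw, nights = NULL, q_low = 0.05, q_high = 0.95,
                              met_threshold = 0.5) {
  cs <- index_and_dedupe(raw)
  cs <- met_artifact_filter(cs, met_threshold)
  cs <- quantile_filter(cs, q_low, q_high)
  if (!is.null(nights)) cs <- annotate_sleep_wake(cs, nights)
  cs
}
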