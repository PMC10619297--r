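# Per-participant temperature variability: state subsetting with hourly
# rolling smoothing, mean/variance, CV, proportional variability (PV),
# consecutive disparity (D), cumulative error, and cycle-phase alignment.

values_of <- function(x) {
  if (inherits(x, "state_series")) x$value
  else if (is.data.frame(x) && "value" %in% names(x)) x$value
  else as.numeric(x)
}

check_positive <- function(v, what) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop(sprintf("undefined metric: %s requires strictly positive values %s",
                 what, "(compute on absolute temperature, not deviations)"),
         call. = FALSE)
  invisible(v)
}

#' Subset a cleaned series to a time state and apply hourly smoothing
#'
#' Keeps the samples of the requested state (`"all24h"` keeps sleep and
#' wake, excluding `unknown`), then smooths with a trailing 60-minute
#' rolling mean computed within contiguous state bouts only, so wake values
#' never leak into sleep bouts. A bout breaks at any state change or
#' timestamp gap larger than the sampling interval. Positions where fewer
#' than `min_frac` of the window's samples are available (bout starts) are
#' dropped.
#'
#' @param s A `clean_series` with a `state` column, or a data.frame with
#'   pid, timestamp, temperature, state.
#' @param state One of `"all24h"`, `"wake"`, `"sleep"`.
#' @param window_minutes Rolling window length (default 60).
#' @param min_frac Minimum fraction of window samples required (default 0.5).
#' @return Object of class `state_series`: data.table pid, timestamp, state,
#'   value (smoothed deg C), with the state kept as attribute `state`.
#' @export
state_subset_and_smooth <- function(s, state = c("all24h", "wake", "sleep"),
                                    window_minutes = 60, min_frac = 0.5) {
  state <- match.arg(state)
  dt <- if (inherits(s, "clean_series")) s$data else data.table::as.data.table(s)
  stopifnot(all(c("pid", "timestamp", "temperature", "state") %in% names(dt)))
  keepstates <- if (state == "all24h") c("wake", "sleep") else state
  dt <- dt[dt$state %in% keepstates]
  if (nrow(dt) == 0L)
    stop(sprintf("insufficient data: no samples in state '%s'", state),
         call. = FALSE)
  dt <- data.table::copy(dt)
  data.table::setorderv(dt, c("pid", "timestamp"))
  step <- dt[, if (.N > 1) stats::median(diff(as.numeric(timestamp))) else 60,
             by = "pid"]
  dt <- step[dt, on = "pid"]
  data.table::setnames(dt, "V1", ".step")
  out <- dt[, {
    tn <- as.numeric(timestamp)
    newbout <- c(TRUE, diff(tn) > .step[1] + 1e-6 |
                       state[-1] != state[-length(state)])
    bout <- cumsum(newbout)
    w <- max(1L, as.integer(round(window_minutes * 60 / .step[1])))
    need <- ceiling(w * min_frac)
    sm <- unlist(lapply(split(temperature, bout), function(v) {
      cs <- cumsum(v)
      i <- seq_along(v)
      k <- pmin(i, w)
      m <- (cs - c(rep(0, min(w, length(v))), cs[seq_len(max(0, length(v) - w))])) / k
      m[k < need] <- NA_real_
      m
    }), use.names = FALSE)
    list(timestamp = timestamp, state = state, value = sm)
  }, by = "pid"]
  out <- out[!is.na(value)]
  if (nrow(out) == 0L)
    stop("insufficient data: no complete smoothing windows", call. = FALSE)
  data.table::setattr(out, "state", state)
  data.table::setattr(out, "class", c("state_series", class(out)))
  out[]
}

#' Mean and sample variance of a state series
#'
#' @param ss A `state_series` or numeric vector (>= 2 values).
#' @return list(mean, variance) with the n-1 variance convention.
#' @export
mean_variance <- function(ss) {
  v <- values_of(ss)
  if (length(v) < 2L)
    stop("insufficient data: need at least 2 values", call. = FALSE)
  list(mean = mean(v), variance = stats::var(v))
}

#' Coefficient of variation
#'
#' CV = sample standard deviation / mean.
#'
#' @param ss A `state_series` or numeric vector.
#' @return Dimensionless CV.
#' @export
cv <- function(ss) {
  v <- values_of(ss)
  if (length(v) < 2L)
    stop("insufficient data: need at least 2 values", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("undefined metric: CV requires a nonzero mean", call. = FALSE)
  stats::sd(v) / m
}

#' Proportional variability index
#'
#' PV = 2 * sum over all pairs (i < j) of (1 - min(z_i, z_j) / max(z_i, z_j))
#' divided by n(n-1): the average proportional difference over all pairs of
#' measurements, in `[0, 1]` for positive data and independent of the mean.
#' Computed in O(n log n) by sorting (for sorted positive values the pair
#' ratio min/max is z_i / z_j with i < j, so the pair sum reduces to prefix
#' sums); agrees with the brute-force pairwise sum to numerical precision.
#'
#' @param ss A `state_series` or numeric vector of strictly positive values.
#' @return PV in `[0, 1]`.
#' @export
pv <- function(ss) {
  v <- values_of(ss)
  n <- length(v)
  if (n < 2L) stop("insufficient data: need at least 2 values", call. = FALSE)
  check_positive(v, "PV")
  z <- sort(v)
  cs <- cumsum(z)
  # sum over i<j of z_i/z_j, with z ascending
  ratio_sum <- sum(c(0, cs[-n]) / z)
  pairs <- n * (n - 1) / 2
  2 * (pairs - ratio_sum) / (n * (n - 1))
}

#' Consecutive disparity index
#'
#' D = mean absolute log-ratio of consecutive values,
#' `(1/(n-1)) * sum |ln(p_{i+1} / p_i)|`: an order-sensitive,
#' scale-invariant rate of change.
#'
#' @param ss A `state_series` or numeric vector of strictly positive values
#'   in chronological order.
#' @return D >= 0.
#' @export
d_index <- function(ss) {
  v <- values_of(ss)
  n <- length(v)
  if (n < 2L) stop("insufficient data: need at least 2 values", call. = FALSE)
  check_positive(v, "D")
  mean(abs(log(v[-1] / v[-n])))
}

#' Cumulative error of a series against a static population reference
#'
#' Per-timepoint static error `se_i = ((t_i - m_p) / s_p) - 1` (the
#' `"printed"` form) or `se_i = |t_i - m_p| / s_p - 1` (the `"absolute"`
#' form, under which values within one population sd of the mean contribute
#' negatively), accumulated as a running sum. The reference `m_p` and `s_p`
#' are a static population mean and sd, typically from
#' [population_reference()].
#'
#' @param values Numeric series for one participant (chronological).
#' @param m_p Population reference mean (deg C).
#' @param s_p Population reference sd (deg C), > 0.
#' @param form `"printed"` (default) or `"absolute"`.
#' @return data.table: t (1-based index), se, cum.
#' @export
cumulative_error <- function(values, m_p, s_p,
                             form = c("printed", "absolute")) {
  form <- match.arg(form)
  if (!is.numeric(s_p) || length(s_p) != 1L || !is.finite(s_p) || s_p <= 0)
    stop_config("s_p", "must be a positive number")
  v <- as.numeric(values)
  se <- if (form == "printed") (v - m_p) / s_p - 1 else abs(v - m_p) / s_p - 1
  data.table::data.table(t = seq_along(v), se = se, cum = cumsum(se))
}

#' Static population reference for cumulative error
#'
#' The reference mean is the mean of per-participant means and the
#' reference sd the mean of per-participant sds within the comparison
#' population.
#'
#' @param values_by_pid Named list of numeric series, one per participant.
#' @return list(m_p, s_p).
#' @export
population_reference <- function(values_by_pid) {
  ms <- vapply(values_by_pid, mean, numeric(1))
  ss <- vapply(values_by_pid, stats::sd, numeric(1))
  list(m_p = mean(ms), s_p = mean(ss))
}

#' Cumulative-error trajectories for a cohort
#'
#' Computes each participant's cumulative error against their own
#' category's static reference (mean of per-participant means, mean of
#' per-participant sds).
#'
#' @param values_by_pid Named list of numeric series.
#' @param labels data.frame with pid, category.
#' @param form See [cumulative_error()].
#' @return data.table: pid, category, t, se, cum.
#' @export
cumulative_error_table <- function(values_by_pid, labels,
                                   form = c("printed", "absolute")) {
  form <- match.arg(form)
  lb <- data.table::as.data.table(labels)
  out <- lapply(names(values_by_pid), function(id) {
    cat <- lb[pid == id, category][1]
    members <- intersect(lb[category == cat, pid], names(values_by_pid))
    ref <- population_reference(values_by_pid[members])
    ce <- cumulative_error(values_by_pid[[id]], ref$m_p, ref$s_p, form)
    ce[, `:=`(pid = id, category = cat)]
    ce
  })
  data.table::rbindlist(out)[, c("pid", "category", "t", "se", "cum"),
                             with = FALSE]
}

# Fold a nightly series on its period into n_bins phase bins and return the
# mean waveform (NA for empty bins).
fold_cycle <- function(x, period, n_bins = 64) {
  t <- seq_along(x) - 1
  b <- floor(((t %% period) / period) * n_bins) + 1
  w <- rep(NA_real_, n_bins)
  agg <- tapply(x, b, mean)
  w[as.integer(names(agg))] <- agg
  w
}

#' Estimate the cycle phase of a nightly series
#'
#' Folds the (mean-centered) series on the given period, then finds the
#' circular shift maximizing the correlation of the folded waveform with a
#' one-period template whose day 0 is the temperature nadir preceding the
#' rise (default template: `-cos`). Returns the estimated location of cycle
#' day 0 in days since the series start, in `[0, period)`.
#'
#' @param x Numeric nightly series.
#' @param period Cycle period in days.
#' @param template Optional numeric template waveform (length `n_bins`),
#'   e.g. from [build_cycle_template()].
#' @param n_bins Phase resolution of the fold (default 64).
#' @return Estimated phase of cycle day 0, days in `[0, period)`.
#' @export
estimate_cycle_phase <- function(x, period, template = NULL, n_bins = 64) {
  x <- as.numeric(x) - mean(x, na.rm = TRUE)
  w <- fold_cycle(x, period, n_bins)
  if (anyNA(w)) {
    idx <- which(!is.na(w))
    w <- stats::approx(idx, w[idx], xout = seq_len(n_bins), rule = 2)$y
  }
  tpl <- template %||% (-cos(2 * pi * (seq_len(n_bins) - 1) / n_bins))
  tpl <- tpl - mean(tpl)
  w <- w - mean(w)
  scores <- vapply(seq_len(n_bins) - 1L, function(s) {
    sum(w[((seq_len(n_bins) - 1L + s) %% n_bins) + 1L] * tpl)
  }, numeric(1))
  best <- which.max(scores) - 1L
  (best / n_bins) * period
}

#' Build a cohort-level one-cycle template waveform
#'
#' First-pass phases are estimated against a sinusoidal template; each
#' cyclic participant's series is then folded on its own period, circularly
#' shifted to put cycle day 0 first, and the z-scored waveforms are
#' averaged across participants.
#'
#' @param series_list Named list of nightly series (cyclic participants).
#' @param periods Numeric vector of matching cycle periods (days).
#' @param n_bins Phase resolution (default 64).
#' @return Numeric template of length `n_bins` (mean-centered).
#' @export
build_cycle_template <- function(series_list, periods, n_bins = 64) {
  stopifnot(length(series_list) == length(periods))
  folded <- mapply(function(x, p) {
    ph <- estimate_cycle_phase(x, p, n_bins = n_bins)
    w <- fold_cycle(as.numeric(x) - mean(x), p, n_bins)
    if (anyNA(w)) {
      idx <- which(!is.na(w))
      w <- stats::approx(idx, w[idx], xout = seq_len(n_bins), rule = 2)$y
    }
    s <- as.integer(round((ph / p) * n_bins)) %% n_bins
    w <- w[((seq_len(n_bins) - 1L + s) %% n_bins) + 1L]
    sdw <- stats::sd(w)
    if (sdw > 0) (w - mean(w)) / sdw else w * 0
  }, series_list, periods)
  rowMeans(folded)
}

#' Align a cyclic participant's nightly series by cycle phase
#'
#' Circularly shifts the series so that the estimated cycle day 0 (see
#' [estimate_cycle_phase()]) falls at the first position, making cycle
#' phases coincide across participants.
#'
#' @param x Numeric nightly series.
#' @param period Cycle period in days; `NA` (acyclic) is an error.
#' @param template Optional template passed to [estimate_cycle_phase()].
#' @param n_bins Phase resolution.
#' @return list(values, shift_days, period).
#' @export
phase_align <- function(x, period, template = NULL, n_bins = 64) {
  if (is.na(period))
    stop("not applicable: phase alignment requires a cyclic participant",
         call. = FALSE)
  ph <- estimate_cycle_phase(x, period, template, n_bins)
  k <- as.integer(round(ph)) %% length(x)
  vals <- if (k == 0) as.numeric(x) else c(x[(k + 1):length(x)], x[1:k])
  list(values = vals, shift_days = k, period = period)
}

#' Per-participant state metrics table
#'
#' For each participant and each time state (24 h, wake, sleep), applies
#' [state_subset_and_smooth()] and computes mean, sample variance, CV, PV
#' and D on the smoothed series.
#'
#' @param clean A `clean_series` with sleep/wake annotation (cohort-level).
#' @param states States to compute (default all three).
#' @param window_minutes Smoothing window (default 60).
#' @return data.table: pid, state, mean, variance, cv, pv, d.
#' @export
state_metrics <- function(clean, states = c("all24h", "wake", "sleep"),
                          window_minutes = 60) {
  dt <- if (inherits(clean, "clean_series")) clean$data
        else data.table::as.data.table(clean)
  rows <- list()
  for (st in states) {
    ss <- state_subset_and_smooth(dt, st, window_minutes)
    rows[[st]] <- ss[, {
      mv <- mean_variance(value)
      list(state = st, mean = mv$mean, variance = mv$variance,
           cv = cv(value), pv = pv(value), d = d_index(value))
    }, by = "pid"]
  }
  data.table::rbindlist(rows)[]
}
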