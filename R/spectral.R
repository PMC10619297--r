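# Infradian rhythm strength via continuous Morlet wavelet power averaged
# over the 26--32-day period band of nightly temperature maxima.

#' Continuous Morlet wavelet transform of a nightly series
#'
#' Computes the continuous wavelet transform with a Morlet mother wavelet
#' (nondimensional frequency `omega0 = 6`) by multiplication in the Fourier
#' domain, over a log-spaced scale grid covering periods of roughly
#' `period_range[1]` to `period_range[2]` days at one sample per day.
#' The series is mean-centered (not variance-normalized) first, so
#' amplitude differences between participants remain visible in power.
#' Scales convert to Fourier periods via the Morlet factor
#' `4 * pi / (omega0 + sqrt(2 + omega0^2))`.
#'
#' @param x Numeric nightly series (e.g. nightly temperature maxima) on a
#'   complete daily grid; interpolate gaps
#'   upstream for gappy data.
#' @param dt Sampling interval in days (default 1).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param period_range Length-2 range of periods (days) the scale grid must
#'   span (default 2--64).
#' @param n_scales Number of log-spaced scales (default 64).
#' @param min_length Minimum series length (default 64 nights).
#' @return Object of class `wavelet_spectrum`: list(periods, times, power)
#'   with `power` a non-negative (period x time) matrix of squared moduli.
#' @export
cwt_morlet <- function(x, dt = 1, omega0 = 6, period_range = c(2, 64),
                       n_scales = 64, min_length = 64) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < min_length)
    stop(sprintf("insufficient data: %d nights (< %d required)", n, min_length),
         call. = FALSE)
  if (anyNA(x)) stop("series contains NA; interpolate gaps first", call. = FALSE)
  x <- x - mean(x)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- exp(seq(log(period_range[1] / fourier_factor),
                    log(period_range[2] / fourier_factor),
                    length.out = n_scales))
  # zero-pad to the next power of two to limit wrap-around
  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  k <- c(seq(0, floor(npad / 2)), seq(floor(npad / 2) + 1 - npad, -1))
  omega <- 2 * pi * k / (npad * dt)
  power <- matrix(0, nrow = n_scales, ncol = n)
  norm0 <- pi^(-0.25)
  for (s in seq_len(n_scales)) {
    sc <- scales[s]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- norm0 * sqrt(2 * pi * sc / dt) *
      exp(-(sc * omega[pos] - omega0)^2 / 2)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / npad
    power[s, ] <- Mod(w[seq_len(n)])^2
  }
  structure(list(periods = scales * fourier_factor,
                 times = seq_len(n) - 1, power = power),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d scales (periods %.1f-%.1f d) x %d times\n",
              length(x$periods), min(x$periods), max(x$periods),
              length(x$times)))
  invisible(x)
}

#' Mean wavelet power in a period band
#'
#' Averages the wavelet power over all (period, time) cells whose period
#' lies in `[lo, hi]` days, excluding for each period row the times within
#' one period length of either series edge (a cone-of-influence margin that
#' avoids edge-artifact inflation).
#'
#' @param spec A `wavelet_spectrum` from [cwt_morlet()].
#' @param lo,hi Band bounds in days (default 26--32).
#' @return Mean band power (non-negative scalar).
#' @export
band_power <- function(spec, lo = 26, hi = 32) {
  stopifnot(inherits(spec, "wavelet_spectrum"))
  if (lo >= hi) stop_config("band", "must satisfy lo < hi")
  rows <- which(spec$periods >= lo & spec$periods <= hi)
  if (!length(rows))
    stop_config("band", "contains no grid periods")
  tmax <- max(spec$times)
  total <- 0; cells <- 0L
  for (r in rows) {
    p <- spec$periods[r]
    keep <- spec$times >= p & spec$times <= tmax - p
    if (!any(keep)) next
    total <- total + sum(spec$power[r, keep])
    cells <- cells + sum(keep)
  }
  if (cells == 0L)
    stop("insufficient data: series shorter than twice the band period",
         call. = FALSE)
  total / cells
}

#' Per-participant band power for a cohort
#'
#' Interpolates each participant's nightly temperature-maximum series onto
#' a complete daily grid, runs the Morlet transform, and returns the mean
#' 26--32-day band power. Participants with disqualifying gaps are skipped
#' with a warning.
#'
#' @param nightly Cohort nightly summaries (pid, date, temp_max).
#' @param lo,hi Band bounds in days.
#' @param ... Passed to [cwt_morlet()].
#' @return data.table: pid, mean_power.
#' @export
cohort_band_power <- function(nightly, lo = 26, hi = 32, ...) {
  dt <- data.table::as.data.table(nightly)
  ids <- unique(dt$pid)
  rows <- lapply(ids, function(id) {
    sub <- dt[pid == id]
    bp <- tryCatch({
      y <- fill_daily_gaps(sub$date, sub$temp_max)$values
      band_power(cwt_morlet(y, ...), lo, hi)
    }, error = function(e) NA_real_)
    data.table::data.table(pid = id, mean_power = bp)
  })
  out <- data.table::rbindlist(rows)
  if (anyNA(out$mean_power))
    warning(sprintf("%d participant(s) skipped in band power",
                    sum(is.na(out$mean_power))), call. = FALSE)
  out[!is.na(mean_power)]
}

#' Category-level band-power summary
#'
#' Arithmetic mean and standard error (sd / sqrt(n)) of mean band power per
#' category.
#'
#' @param band_powers data.frame with pid, mean_power.
#' @param labels data.frame with pid, category.
#' @return data.table: category, n, mean, se.
#' @export
group_band_summary <- function(band_powers, labels) {
  bp <- data.table::as.data.table(band_powers)
  lb <- data.table::as.data.table(labels)
  m <- lb[, c("pid", "category")][bp, on = "pid", nomatch = NULL]
  out <- m[, list(n = .N, mean = mean(mean_power),
                  se = stats::sd(mean_power) / sqrt(.N)), by = "category"]
  if (any(out$n < 2))
    stop("standard error undefined for singleton category", call. = FALSE)
  out[]
}
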