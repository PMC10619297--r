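# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_number <- function(x, field, lo = -Inf, hi = Inf, allow_hi = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  if (x < lo || (allow_hi && x > hi) || (!allow_hi && x >= hi))
    stop_config(field, sprintf("must lie in [%g, %g%s", lo, hi,
                               if (allow_hi) "]" else ")"))
  invisible(x)
}

# Deterministic per-participant seed derived from the master seed and the
# participant id, so substreams are independent of generation order.  All
# intermediates stay below 2^53 so the arithmetic is exact in doubles.
participant_seed <- function(pid, seed) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 69069 + 1) %% m
  for (code in utf8ToInt(as.character(pid))) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Place a nightly-value series on a complete daily grid, linearly
# interpolating gaps.  Used by both the autocorrelation and wavelet stages,
# which share the same gap policy: more than `max_frac` missing or any run
# longer than `max_run` nights disqualifies the participant.
fill_daily_gaps <- function(dates, values, max_run = 14, max_frac = 0.2) {
  stopifnot(length(dates) == length(values))
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  grid <- seq(min(dates), max(dates), by = "1 day")
  y <- rep(NA_real_, length(grid))
  y[match(dates, grid)] <- values
  miss <- is.na(y)
  if (any(miss)) {
    if (mean(miss) > max_frac)
      stop(sprintf("insufficient data: %.0f%% of nights missing (limit %.0f%%)",
                   100 * mean(miss), 100 * max_frac), call. = FALSE)
    runs <- rle(miss)
    if (max(runs$lengths[runs$values]) > max_run)
      stop(sprintf("insufficient data: missing-night run longer than %d nights",
                   max_run), call. = FALSE)
    y <- stats::approx(seq_along(y)[!miss], y[!miss], xout = seq_along(y),
                       rule = 2)$y
  }
  list(dates = grid, values = y)
}
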