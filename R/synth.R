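# Synthetic cohort generator: minute-level distal temperature / MET streams
# and nightly sleep summaries with planted circadian and infradian structure.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic wearable cohort.
#' The generator emulates distal (skin) body temperature from a ring sensor:
#' a smooth 24-h circadian waveform, an additive sleep elevation, an optional
#' 26--32-day infradian oscillation of nightly temperature in cyclic
#' participants, state-dependent sensor noise (wider while awake),
#' device-off/charging artifacts (MET < 0.5 with a transient temperature
#' spike), and random missingness.
#'
#' Group structure is controlled by state-specific offsets
#' (`group_wake_offsets`, `group_sleep_offsets`, in deg C) for the three
#' categories `cyclic_female`, `acyclic_female`, `male`, plus a
#' between-participant baseline spread `between_sd`. Between-group Cohen's d
#' for a state mean is therefore (offset difference) / `between_sd` to a
#' close approximation; the defaults plant sleep-mean d of about 1.40
#' (cyclic female vs male) and wake-mean d of about -0.41, with
#' `between_sd = 0.5` deg C.
#'
#' @param n_per_group Named integer vector of participant counts for
#'   `cyclic_female`, `acyclic_female`, `male`, or a single count used for
#'   all three. The default mirrors a 600-person cohort: 300 females (105
#'   cyclic, 195 acyclic) and 300 males.
#' @param start_date First simulated date.
#' @param n_days Number of simulated days.
#' @param sample_minutes Sampling interval in minutes; 1 or 5.
#' @param base_temp Population baseline distal temperature, deg C.
#' @param circadian_amp Amplitude of the 24-h cosine (nadir mid-sleep), deg C.
#' @param sleep_offset Temperature elevation while asleep, deg C.
#' @param cycle_period_days Length-2 range; each cyclic participant's period
#'   is drawn uniformly from it (days).
#' @param cycle_amp Amplitude of the infradian modulation of nightly
#'   temperature in cyclic participants, deg C.
#' @param wake_noise_sd,sleep_noise_sd Minute-level noise sd by state, deg C.
#' @param nightly_noise_sd Night-to-night noise sd of the nightly aggregates
#'   (temperature maximum and trend deviation), deg C.
#' @param between_sd Between-participant sd of the baseline offset, deg C.
#' @param amp_rel_sd,offset_rel_sd Relative between-participant sd of the
#'   circadian amplitude and sleep elevation (individual heterogeneity).
#' @param noise_rel_sd Log-scale between-participant sd of the minute-level
#'   noise magnitude.
#' @param group_wake_offsets,group_sleep_offsets Named numeric vectors
#'   (deg C) of category-level offsets applied during wake and sleep.
#' @param missing_frac Fraction of minute samples deleted at random.
#' @param whole_day_gap_rate Probability that an entire day is missing.
#' @param artifact_rate Expected number of low-MET artifact segments per day.
#' @param seed Master integer seed; per-participant substreams are derived
#'   from it by stable hashing of the participant id.
#' @param age_bins Data frame with columns `lo`, `hi` giving half-open age
#'   bins; participants are spread evenly across bins within each sex.
#'   Default: six decade bins from 20 to 80.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(cyclic_female = 105L,
                                       acyclic_female = 195L,
                                       male = 300L),
                       start_date = as.Date("2020-01-01"),
                       n_days = 180L,
                       sample_minutes = 1L,
                       base_temp = 34.0,
                       circadian_amp = 0.5,
                       sleep_offset = 1.0,
                       cycle_period_days = c(26, 32),
                       cycle_amp = 0.3,
                       wake_noise_sd = 0.35,
                       sleep_noise_sd = 0.15,
                       nightly_noise_sd = 0.1,
                       between_sd = 0.5,
                       group_wake_offsets = c(cyclic_female = -0.205,
                                              acyclic_female = -0.165,
                                              male = 0),
                       group_sleep_offsets = c(cyclic_female = 0.70,
                                               acyclic_female = 0.205,
                                               male = 0),
                       amp_rel_sd = 0.1,
                       offset_rel_sd = 0.1,
                       noise_rel_sd = 0.2,
                       missing_frac = 0.02,
                       whole_day_gap_rate = 0.01,
                       artifact_rate = 0.2,
                       seed = 1L,
                       age_bins = NULL) {
  cats <- c("cyclic_female", "acyclic_female", "male")
  if (length(n_per_group) == 1L && is.null(names(n_per_group)))
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 3L), cats)
  if (!all(cats %in% names(n_per_group)))
    stop_config("n_per_group", "must name cyclic_female, acyclic_female, male")
  n_per_group <- vapply(n_per_group[cats], as.integer, integer(1))
  if (any(n_per_group < 1L)) stop_config("n_per_group", "must be >= 1")
  if (!sample_minutes %in% c(1L, 5L))
    stop_config("sample_minutes", "must be 1 or 5")
  assert_number(n_days, "n_days", lo = 1)
  assert_number(circadian_amp, "circadian_amp", lo = 0)
  assert_number(sleep_offset, "sleep_offset")
  assert_number(cycle_amp, "cycle_amp", lo = 0)
  assert_number(wake_noise_sd, "wake_noise_sd", lo = 0)
  assert_number(sleep_noise_sd, "sleep_noise_sd", lo = 0)
  assert_number(nightly_noise_sd, "nightly_noise_sd", lo = 0)
  assert_number(between_sd, "between_sd", lo = 0)
  assert_number(amp_rel_sd, "amp_rel_sd", lo = 0)
  assert_number(offset_rel_sd, "offset_rel_sd", lo = 0)
  assert_number(noise_rel_sd, "noise_rel_sd", lo = 0)
  assert_number(missing_frac, "missing_frac", lo = 0, hi = 1, allow_hi = FALSE)
  assert_number(whole_day_gap_rate, "whole_day_gap_rate", lo = 0, hi = 1)
  assert_number(artifact_rate, "artifact_rate", lo = 0)
  if (length(cycle_period_days) != 2L || cycle_period_days[1] > cycle_period_days[2] ||
      any(cycle_period_days <= 0))
    stop_config("cycle_period_days", "must be an increasing positive range")
  for (nm in c("group_wake_offsets", "group_sleep_offsets")) {
    v <- get(nm)
    if (!all(cats %in% names(v)))
      stop_config(nm, "must name cyclic_female, acyclic_female, male")
  }
  if (is.null(age_bins))
    age_bins <- data.frame(lo = seq(20, 70, 10), hi = seq(30, 80, 10))
  if (!all(c("lo", "hi") %in% names(age_bins)) || any(age_bins$lo >= age_bins$hi))
    stop_config("age_bins", "must have columns lo < hi")
  cfg <- list(n_per_group = n_per_group,
              start_date = as.Date(start_date), n_days = as.integer(n_days),
              sample_minutes = as.integer(sample_minutes),
              base_temp = base_temp, circadian_amp = circadian_amp,
              sleep_offset = sleep_offset,
              cycle_period_days = as.numeric(cycle_period_days),
              cycle_amp = cycle_amp,
              wake_noise_sd = wake_noise_sd, sleep_noise_sd = sleep_noise_sd,
              nightly_noise_sd = nightly_noise_sd, between_sd = between_sd,
              amp_rel_sd = amp_rel_sd, offset_rel_sd = offset_rel_sd,
              noise_rel_sd = noise_rel_sd,
              group_wake_offsets = group_wake_offsets[cats],
              group_sleep_offsets = group_sleep_offsets[cats],
              missing_frac = missing_frac,
              whole_day_gap_rate = whole_day_gap_rate,
              artifact_rate = artifact_rate,
              seed = as.integer(seed), age_bins = age_bins)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %s\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  cat(sprintf("  horizon: %d days from %s at %d-min sampling\n",
              x$n_days, format(x$start_date), x$sample_minutes))
  cat(sprintf("  cycle: amp %.2f degC, period U(%g, %g) d; seed %d\n",
              x$cycle_amp, x$cycle_period_days[1], x$cycle_period_days[2],
              x$seed))
  invisible(x)
}

# Category label -> sex.
category_sex <- function(category) {
  ifelse(category == "male", "male", "female")
}

#' Build the participant table for a synthetic cohort
#'
#' Draws participant identities, ages (spread evenly over the configured age
#' bins within each sex) and ground-truth cyclicity parameters: cyclic
#' females get a period drawn uniformly from `cfg$cycle_period_days` and a
#' phase uniform on `[0, period)`.
#'
#' @param cfg A [sim_config()].
#' @return A data.table with columns `pid`, `category`, `sex`, `age`,
#'   `age_bin`, `truth_cyclic`, `truth_period_days`, `truth_phase_days`.
#' @export
cohort_participants <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cats <- names(cfg$n_per_group)
  pre <- c(cyclic_female = "CF", acyclic_female = "AF", male = "M")
  with_seed(cfg$seed, {
    rows <- lapply(cats, function(cat) {
      n <- cfg$n_per_group[[cat]]
      data.table::data.table(
        pid = sprintf("%s%04d", pre[[cat]], seq_len(n)),
        category = cat, sex = category_sex(cat))
    })
    dt <- data.table::rbindlist(rows)
    # spread ages evenly over bins within each sex, mirroring an
    # age-bin-balanced cohort design
    nb <- nrow(cfg$age_bins)
    dt[, `:=`(age = NA_real_, age_bin = NA_character_)]
    for (sx in unique(dt$sex)) {
      idx <- which(dt$sex == sx)
      bins <- rep(seq_len(nb), length.out = length(idx))
      lo <- cfg$age_bins$lo[bins]; hi <- cfg$age_bins$hi[bins]
      data.table::set(dt, idx, "age", floor(stats::runif(length(idx), lo, hi)))
      data.table::set(dt, idx, "age_bin", sprintf("%d-%d", lo, hi - 1))
    }
    dt[, truth_cyclic := category == "cyclic_female"]
    dt[, truth_period_days := ifelse(truth_cyclic,
      stats::runif(.N, cfg$cycle_period_days[1], cfg$cycle_period_days[2]),
      NA_real_)]
    dt[, truth_phase_days := ifelse(truth_cyclic,
      stats::runif(.N) * truth_period_days, NA_real_)]
    dt[]
  })
}

# Infradian modulation of nightly temperature, evaluated at (fractional)
# day index d for one participant.
cycle_term <- function(d, p) {
  if (!isTRUE(p$truth_cyclic)) return(rep(0, length(d)))
  p$cycle_amp * sin(2 * pi * (d - p$truth_phase_days) / p$truth_period_days)
}

# Per-participant stable attributes drawn first in the substream so the
# minute-level and nightly-only paths agree on them.
participant_attrs <- function(p, cfg) {
  list(baseline = stats::rnorm(1, 0, cfg$between_sd),
       onset_hour = stats::rnorm(1, 23, 0.5),     # habitual sleep onset
       dur_hours = stats::runif(1, 7.5, 8.5),     # habitual sleep length
       # individual heterogeneity of rhythm amplitude, sleep elevation and
       # sensor noise, so variance-type metrics disperse within groups
       amp = cfg$circadian_amp *
         max(0, 1 + stats::rnorm(1, 0, cfg$amp_rel_sd)),
       sleep_off = cfg$sleep_offset *
         (1 + stats::rnorm(1, 0, cfg$offset_rel_sd)),
       noise_fac = exp(stats::rnorm(1, 0, cfg$noise_rel_sd)))
}

#' Generate one participant's minute-level stream and nightly summaries
#'
#' The temperature model is additive:
#' baseline + state-specific group offset + circadian cosine (nadir at the
#' participant's habitual mid-sleep) + sleep elevation + per-day infradian
#' term (cyclic participants only) + state-dependent Gaussian noise.
#' Charging/non-wear artifacts are 30--60-min segments with MET below 0.5
#' and a +1 deg C spike; `missing_frac` of samples and occasional whole days
#' are deleted. Nightly summaries carry the generator's own aggregates: the
#' temperature maximum over the night's clean sleep samples and a trend
#' deviation equal to the infradian term plus nightly noise.
#'
#' @param participant One row of [cohort_participants()] (data.frame or list
#'   with `pid`, `category`, `truth_*` fields).
#' @param cfg A [sim_config()].
#' @param seed Optional integer overriding the seed derived from
#'   `cfg$seed` and the participant id.
#' @return List with `minute` (data.table: pid, timestamp, temperature, met,
#'   state) and `nightly` (data.table: pid, date, sleep_start, sleep_end,
#'   sleep_duration, temp_max, temp_trend_dev).
#' @export
generate_participant <- function(participant, cfg,
                                 seed = participant_seed(participant$pid,
                                                         cfg$seed)) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- as.list(participant)
  p$cycle_amp <- cfg$cycle_amp
  with_seed(seed, {
    at <- participant_attrs(p, cfg)
    step <- cfg$sample_minutes * 60
    t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
    ts <- t0 + seq(0, cfg$n_days * 86400 - step, by = step)
    n <- length(ts)
    tod_h <- ((as.numeric(ts) - as.numeric(t0)) / 3600) %% 24
    day <- floor((as.numeric(ts) - as.numeric(t0)) / 86400)

    # nightly sleep windows: onset on day d at onset_hour + jitter,
    # duration jittered around the habitual length (7-9 h overall)
    onset_jit <- stats::rnorm(cfg$n_days, 0, 0.5)
    dur <- pmin(9, pmax(7, at$dur_hours + stats::rnorm(cfg$n_days, 0, 0.25)))
    sleep_start <- as.numeric(t0) + (seq_len(cfg$n_days) - 1) * 86400 +
      (at$onset_hour + onset_jit) * 3600
    sleep_end <- sleep_start + dur * 3600

    tnum <- as.numeric(ts)
    state <- rep("wake", n)
    night_of <- rep(NA_integer_, n)
    for (d in seq_len(cfg$n_days)) {
      inside <- tnum >= sleep_start[d] & tnum < sleep_end[d]
      state[inside] <- "sleep"
      night_of[inside] <- d
    }
    asleep <- state == "sleep"

    mid_sleep_h <- (at$onset_hour + at$dur_hours / 2) %% 24
    circ <- -at$amp * cos(2 * pi * (tod_h - mid_sleep_h) / 24)
    g_off <- ifelse(asleep, cfg$group_sleep_offsets[[p$category]],
                    cfg$group_wake_offsets[[p$category]])
    cyc_day <- cycle_term(seq_len(cfg$n_days) - 1L, p)
    noise_sd <- at$noise_fac *
      ifelse(asleep, cfg$sleep_noise_sd, cfg$wake_noise_sd)
    temp <- cfg$base_temp + at$baseline + g_off + circ +
      at$sleep_off * asleep + cyc_day[day + 1L] +
      stats::rnorm(n, 0, 1) * noise_sd
    met <- ifelse(asleep, stats::runif(n, 0.6, 1.0), stats::runif(n, 0.9, 3.0))

    # charging / non-wear artifacts: low MET, transient +1 degC spike
    n_art <- stats::rpois(1, cfg$artifact_rate * cfg$n_days)
    artifact <- rep(FALSE, n)
    if (n_art > 0) {
      starts <- sort(sample.int(n, n_art))
      lens <- ceiling(stats::runif(n_art, 30, 60) / cfg$sample_minutes)
      for (j in seq_len(n_art)) {
        idx <- starts[j]:min(n, starts[j] + lens[j] - 1L)
        artifact[idx] <- TRUE
      }
      temp[artifact] <- temp[artifact] + 1.0
      met[artifact] <- stats::runif(sum(artifact), 0, 0.4)
    }

    # nightly summaries from clean sleep samples
    nightly <- data.table::data.table(
      pid = p$pid,
      date = cfg$start_date + (seq_len(cfg$n_days) - 1L),
      sleep_start = as.POSIXct(sleep_start, origin = "1970-01-01", tz = "UTC"),
      sleep_end = as.POSIXct(sleep_end, origin = "1970-01-01", tz = "UTC"),
      sleep_duration = dur * 60)
    tm <- rep(NA_real_, cfg$n_days)
    ok <- asleep & !artifact
    if (any(ok)) {
      agg <- tapply(temp[ok], night_of[ok], max)
      tm[as.integer(names(agg))] <- agg
    }
    nightly[, temp_max := tm + stats::rnorm(.N, 0, cfg$nightly_noise_sd)]
    nightly[, temp_trend_dev := cyc_day + stats::rnorm(.N, 0, cfg$nightly_noise_sd)]

    minute <- data.table::data.table(pid = p$pid, timestamp = ts,
                                     temperature = temp, met = met,
                                     state = state)
    # missingness: sample-wise plus occasional whole-day gaps
    drop <- stats::runif(n) < cfg$missing_frac
    gap_days <- which(stats::runif(cfg$n_days) < cfg$whole_day_gap_rate)
    if (length(gap_days)) drop <- drop | (day + 1L) %in% gap_days
    minute <- minute[!drop]
    nightly <- nightly[!(seq_len(cfg$n_days) %in% gap_days) & !is.na(temp_max)]
    list(minute = minute, nightly = nightly)
  })
}

#' Generate nightly aggregates directly (fast path)
#'
#' Same nightly model as [generate_participant()] but marginalized to one
#' value per night, skipping minute-level simulation: the nightly
#' temperature maximum is the participant's sleep-state level (baseline +
#' sleep group offset + sleep elevation + circadian value at the sleep-bout
#' edge) plus the infradian term and nightly noise; the trend deviation is
#' the infradian term plus nightly noise. Use it for stages that consume
#' only nightly aggregates (cyclicity, wavelet, nightly cumulative error).
#'
#' @inheritParams generate_participant
#' @return data.table with columns pid, date, temp_max, temp_trend_dev.
#' @export
generate_nightly <- function(participant, cfg,
                             seed = participant_seed(participant$pid,
                                                     cfg$seed)) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- as.list(participant)
  p$cycle_amp <- cfg$cycle_amp
  with_seed(seed, {
    at <- participant_attrs(p, cfg)
    d <- seq_len(cfg$n_days) - 1L
    cyc <- cycle_term(d, p)
    # circadian cosine at the sleep-window edge, where the nightly max sits
    circ_edge <- -at$amp * cos(pi * at$dur_hours / 24)
    level <- cfg$base_temp + at$baseline +
      cfg$group_sleep_offsets[[p$category]] + at$sleep_off + circ_edge
    data.table::data.table(
      pid = p$pid,
      date = cfg$start_date + d,
      temp_max = level + cyc + stats::rnorm(cfg$n_days, 0, cfg$nightly_noise_sd),
      temp_trend_dev = cyc + stats::rnorm(cfg$n_days, 0, cfg$nightly_noise_sd))
  })
}

#' Generate a full synthetic cohort
#'
#' @param cfg A [sim_config()].
#' @param resolution `"minute"` generates minute streams plus nightly
#'   summaries; `"nightly"` uses the fast nightly-only path.
#' @return List with `participants` (truth table), `nightly` (one
#'   data.table for the cohort), and, at minute resolution, `minute`.
#' @export
generate_cohort <- function(cfg, resolution = c("minute", "nightly")) {
  resolution <- match.arg(resolution)
  parts <- cohort_participants(cfg)
  if (resolution == "nightly") {
    nightly <- data.table::rbindlist(
      lapply(seq_len(nrow(parts)), function(i) generate_nightly(parts[i], cfg)))
    return(list(participants = parts, nightly = nightly))
  }
  sims <- lapply(seq_len(nrow(parts)), function(i) generate_participant(parts[i], cfg))
  list(participants = parts,
       minute = data.table::rbindlist(lapply(sims, `[[`, "minute")),
       nightly = data.table::rbindlist(lapply(sims, `[[`, "nightly")))
}

#' Write a synthetic cohort to disk
#'
#' Writes one minute-level file per participant plus a cohort truth table
#' and the nightly summaries. CSV is always available; Parquet requires the
#' `arrow` package.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for parquet output", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, path) {
    if (format == "csv") data.table::fwrite(x, paste0(path, ".csv"))
    else arrow::write_parquet(x, paste0(path, ".parquet"))
  }
  data.table::fwrite(cohort$participants, file.path(dir, "participants.csv"))
  wr(cohort$nightly, file.path(dir, "nightly"))
  if (!is.null(cohort$minute)) {
    mdir <- file.path(dir, "minute")
    dir.create(mdir, showWarnings = FALSE)
    for (id in unique(cohort$minute$pid))
      wr(cohort$minute[cohort$minute$pid == id], file.path(mdir, id))
  }
  invisible(dir)
}
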