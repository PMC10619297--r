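wake_series <- function(temps, by = 60) {
  data.frame(pid = "P1",
             timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
               seq(0, by = by, length.out = length(temps)),
             temperature = temps, state = "wake")
}

test_that("trailing hourly smoothing ramps across a step and respects bouts", {
  s <- wake_series(c(rep(36, 60), rep(37, 60)))
  ss <- state_subset_and_smooth(s, "wake")
  # hand-computed: window k = min(i, 60), kept where k >= 30
  i <- 30:120
  expected <- ifelse(i <= 60, 36, 36 + (i - 60) / 60)
  expect_equal(ss$value, expected)
  # constant series stays constant; full series retained beyond warm-up
  cs <- state_subset_and_smooth(wake_series(rep(36.5, 90)), "wake")
  expect_true(all(cs$value == 36.5))
  expect_equal(nrow(cs), 61L)
  # a 2-hour gap breaks the bout: no smoothing across it
  g <- wake_series(rep(36, 120))
  g$timestamp[61:120] <- g$timestamp[61:120] + 7200
  g$temperature[61:120] <- 38
  sg <- state_subset_and_smooth(g, "wake")
  expect_setequal(unique(sg$value), c(36, 38))
  # requesting a state with no samples errors
  expect_error(state_subset_and_smooth(s, "sleep"), "insufficient")
})

test_that("mean/variance/CV follow the sample (n-1) conventions", {
  mv <- mean_variance(c(36, 38))
  expect_equal(mv$mean, 37); expect_equal(mv$variance, 2)
  expect_equal(mean_variance(rep(5, 10))$variance, 0)
  set.seed(3)
  x <- stats::rnorm(40, 36)
  shifted <- mean_variance(x + 1.5)
  expect_equal(shifted$mean, mean_variance(x)$mean + 1.5)
  expect_equal(shifted$variance, mean_variance(x)$variance)
  expect_error(mean_variance(36), "insufficient")
  expect_equal(cv(c(2, 4)), sqrt(2) / 3)
  expect_equal(cv(rep(3, 5)), 0)
  expect_equal(cv(3 * x), cv(x))
  expect_error(cv(c(-1, 1)), "mean")
})

test_that("PV matches its brute-force pairwise oracle", {
  expect_equal(pv(c(1, 2)), 0.5)
  expect_equal(pv(c(1, 2, 4)), 7 / 12)
  expect_equal(pv(rep(2, 6)), 0)
  set.seed(12)
  for (rep in 1:50) {
    z <- stats::runif(sample(2:200, 1), 0.5, 40)
    expect_equal(pv(z), pv_bruteforce(z), tolerance = 1e-12)
  }
  expect_error(pv(c(1, -2, 3)), "positive")
})

test_that("consecutive disparity is scale- and reversal-invariant", {
  expect_equal(d_index(c(1, 2, 4)), log(2))
  expect_equal(d_index(rep(7, 9)), 0)
  set.seed(14)
  x <- stats::runif(60, 30, 40)
  expect_equal(d_index(5 * x), d_index(x))
  expect_equal(d_index(rev(x)), d_index(x))
  # direct formula evaluation
  expect_equal(d_index(x), mean(abs(diff(log(x)))), tolerance = 1e-12)
  expect_error(d_index(c(1, 0, 2)), "positive")
})

test_that("cumulative error obeys its fixed points and prefix-sum identity", {
  m <- 36; s <- 0.5; n <- 25   # binary-exact reference values
  ce1 <- cumulative_error(rep(m + s, n), m, s)
  expect_equal(ce1$se, rep(0, n))
  expect_equal(ce1$cum, rep(0, n))
  ce2 <- cumulative_error(rep(m, n), m, s)
  expect_equal(ce2$cum[n], -n)
  set.seed(16)
  v <- stats::rnorm(100, m, s)
  ce <- cumulative_error(v, m, s)
  expect_equal(ce$cum, cumsum((v - m) / s - 1), tolerance = 1e-12)
  # additivity over concatenation with a fixed reference
  a <- v[1:40]; b <- v[41:100]
  expect_equal(cumulative_error(c(a, b), m, s)$cum[100],
               cumulative_error(a, m, s)$cum[40] +
                 cumulative_error(b, m, s)$cum[60])
  # absolute form zeroes one-sd deviations on both sides
  ce_abs <- cumulative_error(c(m + s, m - s), m, s, form = "absolute")
  expect_equal(ce_abs$se, c(0, 0))
  expect_error(cumulative_error(v, m, 0), "s_p")
})

test_that("population reference averages per-participant means and sds", {
  vals <- list(a = c(1, 3), b = c(10, 14))
  ref <- population_reference(vals)
  expect_equal(ref$m_p, mean(c(2, 12)))
  expect_equal(ref$s_p, mean(c(sqrt(2), sqrt(8))))
  lab <- data.frame(pid = c("a", "b"), category = "g")
  tab <- cumulative_error_table(vals, lab)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$cum[tab$pid == "a"][2],
               sum((c(1, 3) - ref$m_p) / ref$s_p - 1))
})

test_that("phase alignment brings offset cycles into register", {
  p <- 28
  x1 <- -cos(2 * pi * (0:179) / p)
  x2 <- -cos(2 * pi * ((0:179) - 10) / p)
  a1 <- phase_align(x1, p)
  a2 <- phase_align(x2, p)
  expect_equal(a1$shift_days, 0)   # already aligned: nadir at day 0
  cc <- stats::ccf(a1$values, a2$values, lag.max = 14, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(phase_align(x1, NA_real_), "cyclic")
})

test_that("estimated phases track generator truth within two days", {
  cfg <- sim_config(n_per_group = c(cyclic_female = 20, acyclic_female = 1,
                                    male = 1),
                    n_days = 180, cycle_amp = 0.3, nightly_noise_sd = 0.05,
                    seed = 33)
  parts <- cohort_participants(cfg)
  cyc <- parts[parts$truth_cyclic]
  series <- lapply(seq_len(nrow(cyc)), function(i)
    generate_nightly(cyc[i], cfg)$temp_trend_dev)
  tpl <- build_cycle_template(series, cyc$truth_period_days)
  errs <- vapply(seq_len(nrow(cyc)), function(i) {
    p <- cyc$truth_period_days[i]
    est <- estimate_cycle_phase(series[[i]], p, template = tpl)
    # generator nadir sits three quarters of a period past the planted phase
    truth <- (cyc$truth_phase_days[i] + 0.75 * p) %% p
    d <- abs(est - truth)
    min(d, p - d)
  }, numeric(1))
  expect_lte(mean(errs), 2)
})

test_that("state metrics require positive absolute temperatures for PV and D", {
  mc <- minute_cohort()
  mt <- state_metrics(mc$clean)
  expect_true(all(c("all24h", "wake", "sleep") %in% mt$state))
  expect_true(all(mt$variance >= 0) && all(mt$pv >= 0 & mt$pv <= 1) &&
                all(mt$d >= 0))
  # deviation-scale input (non-positive values) raises the metric error
  dev <- mc$clean$data
  dev$temperature <- dev$temperature - mean(dev$temperature)
  expect_error(state_metrics(dev), "positive")
})
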