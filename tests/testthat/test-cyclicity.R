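test_that("autocorrelation profiles match the lag-product estimator", {
  x <- sin(2 * pi * (0:179) / 28)
  pr <- compute_acf(x, max_lag = 60)
  expect_equal(pr$acf[1], 1, tolerance = 1e-9)
  expect_equal(pr$acf, acf_lagproduct(x, 60), tolerance = 1e-10)
  # local maximum at the planted 28-day period
  pk <- thermovar:::acf_peak(pr, band = c(20, 32))
  expect_lte(abs(pk$period - 28), 1)
  # white noise stays below the Monte-Carlo bound
  set.seed(8)
  wn <- compute_acf(stats::rnorm(180), max_lag = 60)
  expect_lt(max(abs(wn$acf[-1])), 0.25)
  expect_error(compute_acf(stats::rnorm(30)), "insufficient")
})

test_that("ACF gap policy interpolates short gaps and rejects long ones", {
  dates <- as.Date("2020-01-01") + 0:179
  dt <- data.frame(pid = "P1", date = dates,
                   temp_trend_dev = sin(2 * pi * (0:179) / 28))
  gappy <- dt[-c(50:55), ]          # 6-night gap: interpolated
  pr <- compute_acf(gappy, max_lag = 60)
  expect_lte(abs(thermovar:::acf_peak(pr)$period - 28), 1)
  long_gap <- dt[-c(50:70), ]       # 21-night run: disqualifies
  expect_error(compute_acf(long_gap, max_lag = 60), "run longer")
})

test_that("DTW distance equals the brute-force dynamic program", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(dtw_distance(1:5, 1:5), 0)
  set.seed(2)
  for (rep in 1:40) {
    a <- stats::rnorm(sample(2:40, 1))
    b <- stats::rnorm(sample(2:40, 1))
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b), tolerance = 1e-12)
    expect_identical(dtw_distance(a, b), dtw_distance(b, a))
  }
  p1 <- compute_acf(stats::rnorm(100), max_lag = 40)
  p2 <- compute_acf(stats::rnorm(100), max_lag = 50)
  expect_error(dtw_distance(p1, p2), "lag grids")
})

test_that("hierarchical clustering separates planted blobs deterministically", {
  set.seed(6)
  blob <- function(center, n) lapply(seq_len(n), function(i)
    center + stats::rnorm(length(center), 0, 0.02))
  profs <- c(blob(sin(seq(0, 6 * pi, length.out = 50)), 8),
             blob(rep(0, 50), 8))
  d <- dtw_distance_matrix(profs)
  cl <- cluster_profiles(d, k = 2)
  expect_equal(length(unique(cl[1:8])), 1L)
  expect_equal(length(unique(cl[9:16])), 1L)
  expect_false(cl[1] == cl[9])
  # k = n gives singletons; zero distances collapse to one cluster
  expect_equal(sort(unique(cluster_profiles(d, k = 16))), 1:16)
  expect_equal(unique(cluster_profiles(matrix(0, 4, 4), k = 1)), 1L)
  expect_error(cluster_profiles(d, k = 17), "k")
  expect_error(cluster_profiles(matrix(c(0, 1, 2, 0), 2, 2), k = 1),
               "symmetric")
})

test_that("cohort classification recovers generator truth and survives permutation", {
  co <- study_cohort()
  res <- classify_cyclicity(co$nightly)
  m <- merge(res, co$participants[, c("pid", "truth_cyclic")], by = "pid")
  acc <- mean((m$label == "cyclic") == m$truth_cyclic)
  expect_gte(acc, 0.95)
  # participant order must not change the labels
  perm <- co$nightly[sample(nrow(co$nightly)), ]
  res2 <- classify_cyclicity(perm)
  m2 <- merge(res[, c("pid", "label")], res2[, c("pid", "label")], by = "pid")
  expect_true(all(m2$label.x == m2$label.y))
})

test_that("an all-acyclic cohort yields no cyclic labels", {
  cfg <- sim_config(n_per_group = c(cyclic_female = 1, acyclic_female = 15,
                                    male = 15),
                    n_days = 180, cycle_amp = 0, nightly_noise_sd = 0.1,
                    seed = 19)
  co <- generate_cohort(cfg, resolution = "nightly")
  res <- classify_cyclicity(co$nightly)
  expect_equal(sum(res$label == "cyclic"), 0L)
})

test_that("a flat profile swept into a cyclic cluster is overridden to acyclic", {
  set.seed(15)
  lags <- 0:90
  wave <- function() {
    a <- 0.45 + stats::rnorm(1, 0, 0.02)
    c(1, a * cos(2 * pi * lags[-1] / 28) + stats::rnorm(90, 0, 0.01))
  }
  flat <- c(1, stats::rnorm(90, 0, 0.01))
  # strongly negative-sloped profiles form the second, distant cluster
  far <- function() c(1, seq(-0.2, -3, length.out = 90) + stats::rnorm(90, 0, 0.01))
  profs <- c(replicate(8, wave(), simplify = FALSE), list(flat),
             replicate(8, far(), simplify = FALSE))
  names(profs) <- sprintf("P%02d", seq_along(profs))
  profs <- lapply(profs, function(v)
    structure(list(pid = NA, lags = lags, acf = v, source_signal = "x"),
              class = "acf_profile"))
  cl <- cluster_profiles(dtw_distance_matrix(profs), k = 2)
  expect_equal(cl[["P09"]], cl[["P01"]]) # flat profile joins the wave cluster
  res <- assign_labels(cl, profs)
  expect_equal(res$label[res$pid == "P09"], "acyclic")
  expect_true(res$override_applied[res$pid == "P09"])
  expect_true(all(res$label[res$pid %in% sprintf("P%02d", 1:8)] == "cyclic"))
  expect_false(any(res$override_applied[res$pid != "P09"]))
})
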