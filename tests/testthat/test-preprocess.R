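mk_series <- function(temps, mets = rep(1, length(temps)),
                      start = "2020-01-01 00:00:00", by = 60) {
  data.frame(pid = "P1",
             timestamp = as.POSIXct(start, tz = "UTC") +
               seq(0, by = by, length.out = length(temps)),
             temperature = temps, met = mets)
}

test_that("indexing sorts by local time and keeps the first duplicate", {
  s <- mk_series(c(36, 36.5, 37))
  dup <- rbind(s, s[2, , drop = FALSE])
  dup$temperature[4] <- 99
  cs <- index_and_dedupe(dup)
  expect_equal(nrow(cs$data), 3L)
  expect_equal(cs$data$temperature[2], 36.5) # first occurrence wins
  expect_equal(dropped_samples(cs)$reason, "duplicate")
  # already sorted unique input is unchanged
  cs2 <- index_and_dedupe(s)
  expect_equal(as.data.frame(cs2$data), s, ignore_attr = TRUE)
  # shuffled input equals the sort-and-unique oracle
  set.seed(4)
  big <- mk_series(stats::rnorm(50, 36))
  shuf <- big[sample(nrow(big)), ]
  expect_equal(index_and_dedupe(shuf)$data$temperature,
               big$temperature[order(big$timestamp)])
  expect_error(index_and_dedupe(big[0, ]), "empty")
})

test_that("quantile filter matches the order-statistics oracle", {
  set.seed(11)
  s <- mk_series(sample(stats::rnorm(100, 36, 0.5)))
  cs <- quantile_filter(s, 0.05, 0.95)
  qs <- stats::quantile(s$temperature, c(0.05, 0.95), type = 7)
  oracle_keep <- sum(s$temperature >= qs[1] & s$temperature <= qs[2])
  expect_equal(nrow(cs$data), oracle_keep)
  expect_true(all(dropped_samples(cs)$reason == "quantile"))
  # no-op band and degenerate constant series drop nothing
  expect_equal(nrow(quantile_filter(s, 0, 1)$data), 100L)
  expect_equal(nrow(quantile_filter(mk_series(rep(36, 20)), 0.05, 0.95)$data),
               20L)
  expect_error(quantile_filter(s, 0.9, 0.1), "q_low")
})

test_that("MET filter drops strictly below threshold and flags artifacts", {
  s <- mk_series(rep(36, 5), mets = c(1, 0.5, 0.49, 0, 2))
  cs <- met_artifact_filter(s)
  expect_equal(cs$data$met, c(1, 0.5, 2)) # met == 0.5 is retained
  expect_equal(unique(dropped_samples(cs)$reason), "met_artifact")
  expect_equal(nrow(met_artifact_filter(mk_series(rep(36, 3)))$data), 3L)
  expect_error(met_artifact_filter(s[, setdiff(names(s), "met")]), "schema")
})

test_that("charging artifacts planted by the generator are removed entirely", {
  cfg <- sim_config(n_per_group = 1, n_days = 10, sample_minutes = 5,
                    artifact_rate = 1, missing_frac = 0,
                    whole_day_gap_rate = 0, seed = 13)
  g <- generate_participant(cohort_participants(cfg)[1], cfg)
  expect_gt(sum(g$minute$met < 0.5), 0)
  cs <- met_artifact_filter(g$minute)
  expect_true(all(cs$data$met >= 0.5))
  expect_equal(nrow(dropped_samples(cs)), sum(g$minute$met < 0.5))
})

test_that("nightly row selection keeps the longest sleep per date", {
  base <- as.POSIXct("2020-03-01 23:00:00", tz = "UTC")
  two <- data.frame(pid = "P1", date = as.Date("2020-03-01"),
                    sleep_start = base + c(0, 3600),
                    sleep_end = base + c(400, 480) * 60,
                    sleep_duration = c(400, 480))
  expect_equal(select_nightly_rows(two)$sleep_duration, 480)
  one <- two[1, ]
  expect_equal(nrow(select_nightly_rows(one)), 1L)
  # randomized multi-row fixture equals the group-by-max oracle
  set.seed(7)
  n <- 200
  fix <- data.frame(pid = sample(c("A", "B"), n, TRUE),
                    date = as.Date("2020-01-01") + sample(0:9, n, TRUE),
                    sleep_start = base + sample(0:5000, n),
                    sleep_duration = sample(300:500, n, TRUE))
  fix$sleep_end <- fix$sleep_start + fix$sleep_duration * 60
  sel <- select_nightly_rows(fix)
  expect_equal(nrow(sel), nrow(unique(fix[, c("pid", "date")])))
  oracle <- aggregate(sleep_duration ~ pid + date, fix, max)
  m <- merge(as.data.frame(sel), oracle, by = c("pid", "date"))
  expect_true(all(m$sleep_duration.x == m$sleep_duration.y))
})

test_that("sleep annotation uses half-open windows and matches generator truth", {
  night <- data.frame(pid = "P1", date = as.Date("2020-01-01"),
                      sleep_start = as.POSIXct("2020-01-01 23:00:00", tz = "UTC"),
                      sleep_end = as.POSIXct("2020-01-02 07:00:00", tz = "UTC"),
                      sleep_duration = 480)
  s <- mk_series(rep(36, 3))
  s$timestamp <- as.POSIXct(c("2020-01-01 23:00:00", "2020-01-02 07:00:00",
                              "2020-01-02 06:59:00"), tz = "UTC")
  st <- annotate_sleep_wake(s, night)$data$state
  expect_equal(st, c("sleep", "wake", "sleep"))
  # a date with no summary at all is unknown
  s2 <- mk_series(36.2, start = "2020-01-10 12:00:00")
  expect_equal(annotate_sleep_wake(s2, night)$data$state, "unknown")
  # overlapping windows are rejected
  bad <- rbind(night, transform(night, date = date + 1,
                                sleep_start = sleep_start + 3600 * 4,
                                sleep_end = sleep_end + 3600 * 30))
  expect_error(annotate_sleep_wake(s, bad), "overlap")
  # on generator output, annotation recovers the planted states
  mc <- minute_cohort()
  m <- merge(mc$clean$data,
             mc$cohort$minute[, c("pid", "timestamp", "state")],
             by = c("pid", "timestamp"), suffixes = c("", ".truth"))
  known <- m$state != "unknown"
  expect_gte(mean(m$state[known] == m$state.truth[known]), 0.99)
})

test_that("completeness filter applies the 70% average-daily rule", {
  day <- function(pid, date, k) # k samples on one day at 5-min spacing
    data.frame(pid = pid,
               timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
                 seq(0, by = 300, length.out = k),
               temperature = 36, met = 1)
  full <- do.call(rbind, lapply(0:9, function(d)
    day("FULL", as.Date("2020-01-01") + d, 288)))
  half <- do.call(rbind, lapply(0:9, function(d)
    day("HALF", as.Date("2020-01-01") + d, 144)))
  # planted completeness 0.75: alternate full and half days
  mix <- do.call(rbind, lapply(0:9, function(d)
    day("MIX", as.Date("2020-01-01") + d, if (d %% 2) 288 else 144)))
  all3 <- rbind(full, half, mix)
  kept <- completeness_filter(all3, sample_minutes = 5, required_months = NA)
  expect_setequal(kept, c("FULL", "MIX"))
  expect_setequal(completeness_filter(all3, 5, threshold = 0.76,
                                      required_months = NA), "FULL")
  # month-presence rule drops a participant missing a required month
  kept2 <- completeness_filter(all3, 5, required_months = c("2020-01", "2020-02"))
  expect_equal(kept2, character(0))
})

test_that("preprocessing partitions samples and is idempotent", {
  mc <- minute_cohort()
  raw <- mc$cohort$minute
  cs <- mc$clean
  expect_equal(nrow(cs$data) + nrow(cs$dropped), nrow(raw))
  # exactly one reason per dropped sample
  expect_true(all(dropped_samples(cs)$reason %in%
                    c("duplicate", "met_artifact", "quantile")))
  expect_equal(nrow(dropped_samples(cs)),
               nrow(unique(dropped_samples(cs))))
  # every annotated sample carries exactly one state
  expect_true(all(cs$data$state %in% c("wake", "sleep", "unknown")))
  # applying the full chain to its own output changes nothing
  again <- preprocess_series(cs, mc$nights)
  expect_equal(again$data, cs$data)
})
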