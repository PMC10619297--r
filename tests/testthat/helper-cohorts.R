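# Shared synthetic fixtures, built once per test run.

# Nightly-resolution study cohort: 30 cyclic females, 30 acyclic females,
# 30 males; 180 nights; infradian amplitude 0.3 degC over nightly noise sd
# 0.1 degC. Used by the cyclicity and spectral checks.
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_group = c(cyclic_female = 30, acyclic_female = 30,
                                        male = 30),
                        n_days = 180, cycle_amp = 0.3, nightly_noise_sd = 0.1,
                        seed = 42)
      cache <<- c(generate_cohort(cfg, resolution = "nightly"),
                  list(cfg = cfg))
    }
    cache
  }
})

# Small minute-resolution cohort with annotation, for preprocessing and
# metrics checks.
minute_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_group = 3, n_days = 14, sample_minutes = 5,
                        seed = 5)
      co <- generate_cohort(cfg, resolution = "minute")
      nights <- select_nightly_rows(co$nightly)
      clean <- preprocess_series(co$minute, nights)
      cache <<- list(cfg = cfg, cohort = co, nights = nights, clean = clean)
    }
    cache
  }
})

# Brute-force oracles, kept deliberately naive and separate from the
# implementations they check.
pv_bruteforce <- function(z) {
  n <- length(z)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      s <- s + 1 - min(z[i], z[j]) / max(z[i], z[j])
  2 * s / (n * (n - 1))
}

dtw_bruteforce <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
  D[n + 1, m + 1]
}

acf_lagproduct <- function(x, max_lag) {
  x <- x - mean(x)
  denom <- sum(x^2)
  vapply(0:max_lag, function(k) {
    n <- length(x)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / denom
  }, numeric(1))
}
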