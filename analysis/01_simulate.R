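#!/usr/bin/env Rscript
# Build the synthetic study cohorts.
#
# Two cohorts are written under results/data/:
#   * "rhythm" - nightly-resolution, 30 cyclic females / 30 acyclic females /
#     30 males over 180 nights, for the cyclicity and wavelet analyses.
#   * "minute" - minute-level (5-min sampling), 15 per category over 30
#     days, for preprocessing, state metrics and group comparisons.
# Ground-truth cyclicity (period, phase) is recorded in the participant
# tables so later stages can score themselves against the generator.

suppressPackageStartupMessages(library(thermovar))

seed <- 20260101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rhythm_cfg <- sim_config(
  n_per_group = c(cyclic_female = 30, acyclic_female = 30, male = 30),
  n_days = 180, cycle_amp = 0.3, nightly_noise_sd = 0.1, seed = seed)
rhythm <- generate_cohort(rhythm_cfg, resolution = "nightly")
write_cohort(rhythm, file.path(out, "rhythm"))

minute_cfg <- sim_config(n_per_group = 15, n_days = 30, sample_minutes = 5,
                         seed = seed + 1L)
minute <- generate_cohort(minute_cfg, resolution = "minute")
write_cohort(minute, file.path(out, "minute"))

message(sprintf(
  "rhythm cohort: %d participants x %d nights (%d cyclic by construction)",
  nrow(rhythm$participants), rhythm_cfg$n_days,
  sum(rhythm$participants$truth_cyclic)))
message(sprintf("minute cohort: %d participants, %d minute-level samples",
                nrow(minute$participants), nrow(minute$minute)))
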