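#!/usr/bin/env Rscript
# Infradian rhythm strength: Morlet continuous wavelet transform of each
# participant's nightly temperature maxima, power averaged over the
# 26-32-day band, summarized per category with a one-sided rank test of
# the cyclic-vs-acyclic contrast.

suppressPackageStartupMessages({
  library(thermovar)
  library(data.table)
})

nightly <- fread("results/data/rhythm/nightly.csv")
nightly[, date := as.Date(date)]
categories <- fread("results/categories.csv")

bp <- cohort_band_power(nightly, lo = 26, hi = 32)
summ <- group_band_summary(bp, categories)
print(summ)

m <- merge(bp, categories, by = "pid")
cyc <- m[category == "cyclic_female", mean_power]
for (other in c("acyclic_female", "male")) {
  p <- wilcox.test(cyc, m[category == other, mean_power],
                   alternative = "greater")$p.value
  message(sprintf("cyclic > %s band power: one-sided MWU p = %.3g", other, p))
}

fwrite(bp, "results/band_power.csv")
fwrite(summ, "results/band_summary.csv")
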