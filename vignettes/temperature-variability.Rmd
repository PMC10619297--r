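---
title: "Methods: longitudinal variability analysis of wearable distal temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal variability analysis of wearable distal temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermovar)
```

## The scientific question

Distal (skin) body temperature from a ring-worn sensor is a dense,
longitudinal physiological signal: it rises during sleep, falls during
wake, and in many ovulating individuals it also oscillates with a roughly
monthly (infradian, ~26–32 day) period. A long-standing methodological
concern holds that such cycles make female subjects "more variable" and
therefore harder to study. This package implements the full analysis chain
needed to examine that claim quantitatively on wearable temperature data:

1. classify each individual as *cyclic* or *acyclic* directly from their
   nightly temperature (no self-report needed);
2. quantify infradian rhythm strength as wavelet band power;
3. compute per-individual temporal-variability statistics in three time
   states (24 h, wake, sleep); and
4. compare sex/cyclicity groups with rank-based tests and effect sizes,
   including the *cumulative error* a single mistimed measurement would
   accrue against a static population mean.

The original cohort this design targets (minute-level ring data) cannot be
redistributed, so the package ships a synthetic-data generator whose
defaults emulate the published study conditions. Every downstream stage is
exercised end to end against the generator's ground truth.

## The synthetic cohort generator

For participant $i$ at time $t$ the generator draws

$$
T_i(t) = \mu + b_i + g_{c(i),s(t)} + A_i\,c_{24}(t)
       + O_i\,\mathbf{1}[\text{sleep}]
       + a\,\sin\!\left(\tfrac{2\pi (d(t)-\phi_i)}{P_i}\right)\mathbf{1}[\text{cyclic}]
       + \varepsilon_{i}(t),
$$

where $\mu$ is the population baseline (34.0 °C), $b_i \sim N(0,
\sigma_b^2)$ a stable participant offset ($\sigma_b = 0.5$ °C),
$g_{c,s}$ a category-by-state offset, $c_{24}$ a 24-h cosine with nadir at
the participant's habitual mid-sleep, $O_i$ the sleep elevation (1.0 °C
nominal), and $\varepsilon$ Gaussian noise with state-dependent sd (wake
0.35 °C, sleep 0.15 °C) — wake temperature is noisier than sleep, as in
real distal-temperature data. Cyclic participants receive a per-day
infradian term with amplitude $a$ (default 0.3 °C), period $P_i \sim
U(26, 32)$ days and phase $\phi_i \sim U(0, P_i)$; the term is constant
within a day, so it shifts whole-night aggregates rather than minute
noise, matching how monthly rhythms are detected (in nightly summaries).

Individual heterogeneity. $A_i$, $O_i$ and the noise magnitude carry
participant-level jitter (`amp_rel_sd`, `offset_rel_sd` relative sds of
0.1; `noise_rel_sd` log-sd of 0.2). Without it, variance-type metrics are
nearly deterministic within a group and between-group effect sizes on
variances become arbitrarily large; with it they disperse realistically.

Group calibration. The category offsets are state-specific because the
published contrasts differ by state *in opposite directions*: the sleep
mean separates cyclic females from males strongly (Cohen's d ≈ 1.40)
while the wake mean separates them weakly and negatively (d ≈ −0.41).
A single per-category offset cannot produce both, so the generator takes a
wake map and a sleep map. With between-participant spread $\sigma_b$,
a planted offset difference $\Delta$ yields $d \approx \Delta/\sigma_b$;
the defaults plant $\Delta_{sleep} = 0.70$ °C and $\Delta_{wake} =
-0.205$ °C against $\sigma_b = 0.5$ °C.

Artifacts and missingness. Charging/non-wear artifacts are 30–60 min
segments with MET < 0.5 and a +1 °C transient; samples are deleted
uniformly at `missing_frac` plus occasional whole-day gaps, so the
completeness filter has something to do.

Determinism. All draws flow from one master seed; each participant's
substream seed is a stable hash of the participant id, so output is
bit-identical under a fixed seed and independent of generation order.

A nightly-resolution fast path (`generate_nightly()`) emits the same
nightly model marginalized to one value per night, for stages that consume
only nightly aggregates (classification, wavelets, nightly cumulative
error). Its night-to-night noise is the configured `nightly_noise_sd`
directly (0.1 °C by default); the heterogeneity factor applies to
minute-level sensor noise only.

## Preprocessing

The cleaning chain is: local-time indexing and first-occurrence
de-duplication; dropping samples with MET strictly below 0.5 (device off /
charging); then a per-participant quantile band. The band retains samples
within the 0.05–0.95 temperature quantiles (linear-interpolation
quantiles). Two choices deserve note:

* The lower bound is 0.05, not 0.5: a 0.5 lower quantile would discard
  half of each participant's data and contradicts the observed
  distributions this design reproduces. Both bounds are configurable.
* MET filtering runs before the quantile fit so charging spikes cannot
  distort the band. The fitted band is stored on the result and reused on
  re-application, making the full chain idempotent.

Sleep windows from the nightly summaries are half-open
$[\mathrm{start}, \mathrm{end})$, so adjacent windows partition time; when
a date has several candidate summary rows the longest sleep wins, ties
broken by earliest start. Dates with no summary are labelled `unknown` and
excluded from state analyses. The cohort completeness filter keeps
participants whose mean daily completeness is ≥ 70% of the expected
samples per day (1440 or 288 depending on sampling mode — the denominator
is configurable because it depends on device mode), optionally requiring
data in every month of the span.

One caveat discovered on synthetic data: the quantile trim acts on each
participant's pooled wake+sleep distribution, and therefore clips the
cyclic group's higher, infradian-widened sleep values hardest; it
attenuates planted between-group sleep-mean contrasts by roughly 15–20%.
Generator-calibration checks (effect-size recovery) consequently measure
state means with the trim disabled (`q_low = 0, q_high = 1`), while the
analysis scripts run the full chain.

## Cyclicity classification

Per participant, the nightly temperature trend deviation (default; the
nightly maximum is available as an option because reasonable designs can
use either — the two differ by the participant's level, which
autocorrelation removes anyway) over ~6 months is placed on a complete
daily grid. Short gaps are linearly interpolated; more than 20% missing
nights or a missing run longer than 14 nights disqualifies the
participant. The standard biased autocorrelation estimate is computed at
lags 0..90 days (capped at series length − 1; 90 days covers ~3 cycles),
pairwise distances between profiles are exact dynamic-time-warping
distances (absolute local cost, full window, dynamic programming in C++ —
profile lengths of ~90 make exact DP cheap, and exactness buys
determinism and oracle-testability), and average-linkage agglomerative
clustering on the precomputed distance matrix is cut at k = 3. Average
linkage is the standard choice for non-Euclidean distance matrices; the
linkage and cut are configurable since reasonable alternatives exist.

A cluster is labelled cyclic when its mean profile has a local ACF maximum
of at least θ within the 20–32-day lag band. Members of a cyclic cluster
whose own profile lacks such a peak are relabelled acyclic with
`override_applied = TRUE` — this automates the manual reassignment of the
occasional non-cyclic individual that DTW distance sweeps into a cyclic
cluster. The default θ is 0.30 ACF units: white-noise ACF profiles of
180-night series stay below ≈ 0.25 (Monte-Carlo bound), so 0.30 keeps
pure-noise peaks out, while a genuine 0.3 °C cycle over 0.1 °C nightly
noise peaks near 0.8. A lower θ admits singleton noise clusters as
"cyclic"; a higher one loses weak cyclers. Males are analysed as one
category regardless of label; females split into cyclic/acyclic.

## Wavelet band power

Rhythm strength is the mean power of the continuous Morlet wavelet
transform (nondimensional frequency ω₀ = 6) of the nightly temperature
maxima, averaged over the 26–32-day period band. The scale grid is 64
log-spaced scales covering periods 2–64 days (bracketing the band with
margin); scale converts to period by the Morlet factor
$4\pi/(\omega_0 + \sqrt{2+\omega_0^2})$. Series are mean-centered but not
variance-normalized, so amplitude differences between groups remain
visible in power. A cone-of-influence margin — times within one period
length of either edge, per scale — is excluded from the average to avoid
edge-artifact inflation. Absolute power depends on normalization
conventions, so only orderings and ratios between groups are meaningful;
the tests assert orderings, never absolute values.

## Variability metrics

Within each time state (24 h = wake ∪ sleep, wake, sleep) the series is
smoothed by a trailing 60-minute rolling mean computed inside contiguous
state bouts only (a bout breaks at a state change or timestamp gap), with
at least 50% of the window present — so wake values never leak into sleep
bouts. On the smoothed values:

* mean and sample variance (n − 1 throughout; the convention is stated
  because either is defensible),
* CV = sd / mean,
* PV $= \frac{2}{n(n-1)} \sum_{i<j} \left(1 -
  \frac{\min(z_i,z_j)}{\max(z_i,z_j)}\right)$, computed in O(n log n) by
  sorting (for sorted values each pair ratio is $z_i/z_j$, reducing the
  double sum to prefix sums) and verified against the O(n²) brute force,
* D $= \frac{1}{n-1}\sum |\ln(p_{i+1}/p_i)|$, order-sensitive and
  scale-invariant.

PV and D require strictly positive inputs (log and min/max ratios), so
they are computed on absolute °C, never on deviation signals; deviation
input raises an error rather than silently shifting.

Cumulative error uses the static error
$SE_i = (t_i - m_p)/s_p - 1$ with a static population reference: $m_p$ is
the mean of per-participant means and $s_p$ the mean of per-participant
sds within the comparison population. The signed form is the default; an
absolute-value variant $|t_i - m_p|/s_p - 1$ (under which values within
one sd contribute negatively) is available behind `form = "absolute"`
because the verbal description of the statistic ("more than one sd from
the mean") and its printed formula pull in different directions. The
trajectory is the prefix sum; group comparison uses Kruskal–Wallis on the
final sums at a threshold of 0.01/4 = 0.0025 (a Bonferroni split over the
four resolution/alignment settings examined).

Phase alignment (for displaying cyclic trajectories in cycle time) folds
each nightly series on its estimated period, estimates the location of
cycle day 0 — the temperature nadir preceding the rise — by maximizing
circular cross-correlation with a one-cycle template, and circularly
shifts the series so day 0 coincides across participants. The template is
the z-scored mean one-cycle waveform of the cyclic group after period
normalization (first-pass phases against a sinusoid); this construction
is the package's own, since phase alignment admits many designs. Note a
circular shift leaves the *final* cumulative sum unchanged; alignment
matters for trajectory shape, not the end-point test.

## Group comparisons

Pairwise Mann–Whitney–Wilcoxon tests are two-sided, exact for small
tie-free samples and normal-approximated with tie correction otherwise
(the `stats::wilcox.test` rules). The 9-comparison Bonferroni family is
{3 group pairs} × {3 time states} for a given metric; age-bin contrasts
of per-participant median nightly maxima test every (below-50 × 50-plus)
bin pair under a family of 15 (all bin pairs of a six-bin design). The
reported U is min(U₁, U₂), which does not depend on pair orientation
(U₁ + U₂ = n₁n₂ always). Cohen's d uses the pooled-sd form. Kruskal–Wallis
handles the all-tied degenerate case by reporting H = 0 with a warning.

## Problem sizes and numerical choices

The shipped analyses and checks use: a nightly-resolution rhythm cohort of
90 participants × 180 nights (30 per category, cycle amplitude 0.3 °C,
nightly noise 0.1 °C); a minute-resolution cohort at 5-min sampling over
30 days for state metrics; n = 300/group at 5-min × 30 days for
effect-size recovery; 100–200 replicates for null calibrations. These
sizes give classification accuracy and band-power contrasts comfortable
margins while keeping any single stage to a couple of minutes on one core.
Tolerances: metric oracles agree to 1e-12; DTW equals its brute-force DP
exactly; ACF peaks are located to ±1 day; recovery of a planted Cohen's d
of 1.40 at n = 300/group is accepted within ±0.15 (the Monte-Carlo sd of
the estimate itself is ≈ 0.09).

## What passing tests do and do not show

The generator is an additive Gaussian model with planted effects. Passing
its checks demonstrates that the pipeline recovers known structure —
cyclicity labels, band-power orderings, configured effect sizes, null
calibration of the tests — not that real wearable data satisfy the model.
In particular:

* real distal temperature has autocorrelated physiological noise,
  behavioral confounds (alcohol, exercise, illness), and device drift,
  none of which are simulated;
* under the fixed study conditions (0.3 °C cycle over 0.1 °C nightly
  noise) the infradian term dominates within-group variance spread, so
  variance-type effect sizes on synthetic data are far larger than
  anything seen in real cohorts; treat them as internal contrasts only;
* no hormonal physiology is modelled — no birth-control effects,
  pregnancy, or perimenopause; cycle amplitude distributions in real
  populations are unknown, and the defaults are calibration knobs, not
  claims about physiology.

## Known limitations

Timestamps are treated as already-local (no timezone arithmetic); the
quantile filter interacts with planted group contrasts as described
above; exact DTW is O(L²) per pair, fine at L ≈ 90 but not intended for
minute-level series; and the wavelet stage reports band power without a
red-noise significance test, which the surrounding comparisons do not
require.
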