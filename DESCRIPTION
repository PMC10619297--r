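Package: thermovar
Title: Longitudinal Variability Analysis of Wearable Distal Body Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for minute-level distal body temperature and
    activity streams from wearable ring sensors. Classifies individuals as
    cyclic or acyclic from nightly temperature via autocorrelation profiles,
    dynamic-time-warping distances and hierarchical clustering; quantifies
    infradian rhythm strength with Morlet continuous wavelet band power;
    computes temporal variability indices (coefficient of variation,
    proportional variability, consecutive disparity) and cumulative-error
    trajectories across sleep, wake and 24-hour states; and compares
    sex/cyclicity groups with rank-based tests and Cohen's d effect sizes.
    Includes a synthetic cohort generator with planted circadian and
    infradian structure so the full pipeline is testable without access to
    proprietary wearable data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    ggplot2
Config/testthat/edition: 3
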