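Package: spindlehd
Title: Individual Sleep-Spindle Detection and Statistics for High-Density EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects individual sleep spindles in high-density EEG sleep
    recordings and analyses them at the single-event level. Detection runs
    on canonical (region-averaged) time series using a b-spline wavelet
    band-pass filter, a 100 ms power envelope and per-cycle median-absolute-
    deviation thresholds; detected events are refined at the channel level
    with Welch band-power ratios, topographic typing (frontal, posterior,
    co-occurring), globality, amplitude, duration and regional peak
    frequencies. Statistical tools include linear mixed models on individual
    spindles with participant random intercepts, covariate residualization,
    stepwise-AIC covariate selection, likelihood-ratio tests, and
    channel-space inference via threshold-free cluster enhancement (TFCE)
    with max-statistic permutation correction. A synthetic hd-EEG generator
    with ground-truth spindles supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
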