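---
title: "Detecting and analysing individual sleep spindles in hd-EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing individual sleep spindles in hd-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlehd)
```

## The problem

Sleep spindles are transient 10–16 Hz oscillations of NREM sleep, lasting
roughly 0.3–3 s, with a characteristic waxing–waning envelope. Much of the
literature quantifies them through band power averaged over whole sleep
stages, which confounds event rate, amplitude, duration, spatial spread and
frequency. `spindlehd` instead detects *individual* spindle events on
high-density recordings and carries every event, with its full parameter
set, into the statistical analysis, so that condition effects can be
attributed to specific spindle properties.

## The detection model

Detection runs in three stages.

**Canonical region series.** Channels are grouped into a 3×3 grid of scalp
regions (frontal/central/posterior × left/mid/right), built in the
azimuthal projection of the sensor positions: nine seed points at
`{-0.5, 0, 0.5}` of the projected head radius, each channel assigned to its
nearest seed if within `radius_frac` (default 0.25) of the head radius.
Averaging the member channels of each region yields nine *canonical* time
series. Spindles are spatially coherent within a region, so the average
raises their signal-to-noise ratio against channel noise, and nine traces
are far cheaper to scan than 64–256 channels.

**Envelope thresholding.** Each canonical trace is band-passed with a
zero-phase cubic-B-spline-windowed carrier. The window support is chosen so
the −3 dB points of the kernel's magnitude response fall exactly on the
band edges (10 and 16 Hz by default); being symmetric, the kernel adds no
phase delay, which keeps event timing unbiased. The filtered trace is
squared and smoothed with a 100 ms moving average (edge-truncated, so the
envelope does not dip spuriously at the series boundaries). Events are
runs of envelope above a *high* threshold, extended to the surrounding
crossings of a *low* threshold, kept if the low-to-low span lasts
300–3000 ms. Thresholds are computed per NREM cycle (a single global
threshold is available as an option), from the median absolute deviation
over the artifact-free samples of that cycle, with multipliers 4 (high)
and 2 (low).

The *scale* on which the MAD is taken matters more than the multipliers.
Three modes are implemented:

* `mad_amplitude` (default): MAD of the band-filtered signal amplitude,
  squared into envelope units — thresholds `(k · MAD)²`.
* `mad_only`: `k · MAD` of the power envelope itself.
* `median_plus_mad`: `median + k · MAD` of the envelope.

For a squared signal the MAD sits close to the median, so both envelope
modes put even the "high" threshold only ~2–3× above typical background
power; on simulated recordings with ground truth this admits several
background excursions per minute that survive the duration rule, and
detection F1 saturates near 0.75. The amplitude-scale mode — the scale on
which classical amplitude-threshold spindle detectors operate — places the
high threshold at roughly 7× the background band power, and recovers
injected spindles with F1 ≈ 0.93–0.95 at band SNR 2 while the multipliers
remain 4×/2× MAD. That empirical separation is why `mad_amplitude` is the
default; the envelope modes remain available and fully tested.

Events that overlap in time across *different* regions are one underlying
spindle: merged transitively (start = earliest member start, end = latest
member end, peak envelope = maximum over members). A merged event may
therefore exceed the per-region 3 s bound; merged events are deliberately
not re-filtered. Events touching a marked artifact by even one sample are
dropped.

**Channel-level refinement.** For each merged event, every channel's Welch
PSD over the event interval (Hamming windows of ≤256 ms, 50% overlap,
zero-padded to a ≤0.25 Hz grid) gives its spindle-band power (11–15 Hz),
its *power ratio* — band power over the mean of the 8–10 and 16–18 Hz
flanks — and its peak frequency. A channel *expresses* the spindle if its
ratio exceeds 1.5 (strictly), i.e. the spindle band is more than 50%
stronger than its surroundings; this guards against broadband bursts such
as arousals. Derived per-event measures:

* **globality** — percent of channels expressing the event;
* **type** — *posterior* if the best posterior-region band power is ≥50%
  larger than the best frontal-region power, *frontal* in the mirror case,
  *co-occurring* otherwise;
* **amplitude** — largest peak-to-peak excursion of the band-filtered
  canonical traces of the member regions (filtered rather than raw, for
  robustness to low-frequency background);
* **peak frequencies** — estimated separately for the three midline
  regions, since spindle frequency famously decreases from posterior to
  frontal sites;
* **summary power/ratio** — maximum over expressing channels (an event
  with no expressing channel is retained but flagged, with the summary
  taken over all channels, so detection and refinement stay separately
  auditable).

Two deliberate band choices coexist: detection filters at 10–16 Hz, while
power/ratio/peak-frequency use 11–15 Hz with 8–10/16–18 Hz flanks; the
gaps at 10–11 and 15–16 Hz belong to neither numerator nor denominator.
Both are configurable.

*Incidence* is unique merged events per minute of artifact-free N2/N3
(per-channel incidence counts only events expressed at that channel). NREM
cycles are maximal runs of N2/N3 epochs of ≥30 min, tolerating at most one
N1 epoch per run — the second N1, or any wake or REM epoch, ends the run.

## Individual-spindle statistics

Spindles from one participant are not independent, so per-event analyses
use linear mixed models with a participant random intercept, fitted by
maximum likelihood (not REML — model comparisons use likelihood-ratio
tests, which require ML). Predictors are split into *key predictors*,
whose full interaction seeds the model and whose effects are tested, and
*candidate covariates*. To keep covariates from inflating key-effect
variance, each covariate is first replaced by its residuals from an OLS
regression on the key-predictor design. A stepwise-AIC search on the
fixed-effects-only model then adds candidate covariates, or their two-way
interactions with in-model terms, or drops non-seed terms (respecting
marginality; seed terms are never dropped; ties break lexicographically so
the search is deterministic). The main effect of a key predictor is a
likelihood-ratio test of the selected model against the model with the
predictor *and every term containing it* removed — which is why a
two-level factor can carry more than one degree of freedom.

## Topographic statistics

Channel-space tests face a multiple-comparisons problem over ~64–256
correlated sensors. The package fits the identical model per channel
(mixed model, or a paired t on participant means), enhances the resulting
T-map with threshold-free cluster enhancement — each channel integrates
`extent(h)^E · h^H · dh` over a ladder of thresholds `h`, where the extent
is the size of its suprathreshold connected component on the sensor
adjacency graph — and corrects family-wise with the max-statistic rule:
one null distribution of per-permutation maximum enhanced values, each
channel's p-value being the proportion of null maxima at or above its
observed value (add-one corrected by default, raw proportion available).
Exchangeability is respected by the relabelling scheme: within-subject
factors are shuffled inside each participant, preserving per-participant
level counts exactly; between-subject factors permute participants as
whole blocks; multiple factors are relabelled sequentially with
independent draws.

Numerical choices: TFCE uses `E = 0.5`, `H = 2` (the conventional
channel-space exponents) and 100 threshold steps up to the map maximum —
with ~50 steps the right-endpoint Riemann sum already deviates ~3% from
the closed-form enhancement of a uniform map, with 100 it is within 1.5%.
Negative statistics are enhanced on the negated map and re-negated.
Channels whose fit fails get `NA` T-values and are excluded from null
maxima. Adjacency connects channels within 1.3× the median
nearest-neighbour sensor distance, a montage-density-independent rule.
Permutation count defaults to 2500; a degenerate paired t (zero variance,
non-zero mean) is capped at a large finite value rather than infinity.

## The synthetic-data generator

`generate_recording()` emulates the study conditions end to end: 500 Hz,
64+ channels on a spiral cap montage, 1/f background noise (spectrally
shaped white noise, per-channel RMS 20 µV), spindles as a Poisson process
at 18 events/min with uniform 0.5–2 s durations, Hann (waxing–waning)
envelopes, Normal frequencies of 11.5 ± 0.5 Hz for frontal and
13.5 ± 0.5 Hz for posterior events (half each by default), Gaussian
topographic spread (σ = 0.45 projected radians) centred on the
frontal-midline or posterior-midline sensor, and non-overlap enforced only
per centre sensor — concurrent frontal/posterior events are allowed and
are exactly what the cross-region merge must absorb. `target_snr` scales
event amplitudes so the event's 10–16 Hz RMS at the centre channel is a
chosen multiple of the background band RMS (the quantity the thresholds
actually see); the derivation uses the analytic band fraction of the noise
shaping, so amplitudes are deterministic given the seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spatially correlated background (real EEG
noise does not average away by `1/sqrt(n)` within a region), slow
oscillations and their coupling to spindles, artifacts, non-stationary
background power across the night, and spindle centres distributed beyond
two midline foci. One visible consequence: with local Gaussian events on a
64-channel cap under an average reference, simulated globality sits near
20%, below the ~50% reported for real 256-channel recordings — wider
simulated spreads do not help, because the average reference begins to
cancel near-global patterns. Recovery scores on synthetic data are
therefore a validation of the machinery, not a clinical performance claim.

`generate_spindle_table()` provides the statistical counterpart: known
fixed effects, Normal participant intercepts and residuals, recorded in a
`truth` attribute for parameter-recovery tests.

## Validation problem sizes

The shipped validation exercises the package at these scales, chosen to
mirror the study conditions while staying desk-sized: one 20-minute
64-channel recording at band SNR 2 for detection recovery (F1, type
agreement, peak-frequency error, incidence, and the with/without-spindles
spectral check); 200 replicates of 20 participants × 200 spindles for
fixed-effect recovery; 1000 replicates of 12 × 40 for likelihood-ratio
calibration; and 200 null datasets of 9 participants × 32 channels × 500
permutations for family-wise error of the TFCE max-statistic correction.
A 2·SE recovery interval has nominal coverage 95.45%, so the 200-replicate
coverage estimate carries a ±1.5% Monte-Carlo standard error and will
occasionally dip below 95% for perfectly nominal estimators.

## Known limitations

* The EDF reader/writer covers continuous 16-bit EDF with a uniform
  sampling rate — no EDF+ discontinuities or annotation decoding.
* Stepwise selection explores two-way interactions only; the per-channel
  mixed-model permutation test refits `n_perm × n_channels` models and is
  the slow path (the paired-t topographic test is vectorised and fast).
* Random effects are intercept-only by design; random slopes would need a
  generalisation of `fit_lmm()`.
* Detection assumes the input is already staged and artifact-marked;
  neither sleep scoring nor bad-channel detection is automated.
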