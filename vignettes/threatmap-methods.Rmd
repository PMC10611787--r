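---
title: "Models and methods behind threatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind threatmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`threatmap` analyzes how aversive stimuli reshape the hippocampal CA1
spatial code in head-fixed treadmill experiments. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic-session generator does and does not emulate,
and the numerical decisions a maintainer should know about. Everything here
describes what the code does; the package's tests and
`scripts/acceptance.R` compute every empirical claim.

## The session model

A session is a single container (`session()`): per-unit sorted spike times
(seconds), a uniformly sampled behavior trace (position in cm on the
half-open circular interval `[0, track_length)`, speed, lap index), an
event log (air puffs, rewards, tail shocks, tones; onset, duration, track
location, epoch index), an optional pyramidal-layer LFP channel, and
context intervals. All bin edges in the package are half-open `[lo, hi)`,
which makes wrap handling unambiguous on the circular track.

Sessions are serialized with R's native RDS format — one file, bit-exact
numeric round trips, which the loader re-validates field by field.
`export_session_csv()` writes the same content as plain-text tables for use
outside R.

Laps are partitioned into alternating no-stimulation and air-puff blocks by
`split_epochs()`: a lap belongs to an air-puff block iff at least one puff
onset falls within it, and each block must be location-contiguous. Epochs
are defined by the stimulation schedule rather than by timestamps, so the
rule is robust to jitter in when exactly a puff fires within a lap.

## Unit classification

The burst index is the ratio of mean autocorrelogram counts in the
(3, 20] ms versus (20, 100] ms lag windows. The autocorrelogram uses 1 ms
bins over ±100 ms with symmetric lags pooled; the windows are half-open so
the 20 ms bin is not double-counted. The bin size and total window are the
package's choice — the index is a ratio of window means, so it is
insensitive to the bin width as long as both windows are well populated. A
unit needs at least 100 spikes for a defined index; an empty reference
window leaves the unit unclassified.

Classification is a pure function of (half-width, burst index):
interneuron below (0.3 ms, 2), pyramidal above both, everything else —
including values exactly on a boundary — unclassified and excluded from
group analyses. Half-width is an input attribute (from sorting metadata or
the generator); waveform extraction happens upstream of this package.

## Stimulus-response detection

For each unit and event type the package builds a trial-averaged PSTH in
20 ms bins over [−4, +4] s around onsets and z-scores it with the mean and
SD of the baseline bins in [−4, 0) s (computed on the trial-averaged PSTH;
a baseline SD below 10⁻⁶ Hz flags a flat baseline and forces class
`none`).

Activation requires z > 2 for at least 50 ms — operationalized as 3
consecutive 20 ms bins, the smallest bin-aligned run of at least 50 ms —
within (0, 3] s after onset, and that requirement must hold both for the
unit's pooled (all-trial) response and consistently across stimulus
locations (2 of 2, 2 of 3, 3 of 4). The two-part structure matters: the
pooled criterion establishes that the unit responds at all, and the
location-consistency rule rejects position-locked artifacts. Because trials
align the animal at the stimulus location, a place field a short run
downstream of one location produces a genuine time-locked rate increase;
only a response reproducible across distant locations can be attributed to
the stimulus. This also constrains the paradigm itself: puff locations must
be separated by more than the track span of the 3 s response window
(45 cm at 15 cm/s), which the generator's auto-spaced locations respect.

Suppression uses z < −1 sustained for at least 200 ms (10 bins,
`suppression_min_s` in the config), with the same pooled + per-location
structure. The longer minimum run is deliberate: sub-threshold silence is
common — for a unit whose pooled baseline expectation is λ per 20 ms bin,
three consecutive empty bins occur under the null with probability roughly
`1 − exp(−146·e^{−3λ})`, which is large for any λ above ~1 — so a 50 ms
suppression rule would classify a sizable fraction of ordinary 2–10 Hz
units as suppressed on stimulus-free data. At 200 ms the null probability
is negligible while real suppressed responses (hundreds of ms to seconds)
are unaffected. A unit meeting both criteria with activation first is
biphasic.

Latency and duration are anchored on the detected response: the starting
bin is the first bin of the contiguous z > 1 (z < −1) stretch that
contains the detection run. Anchoring matters for low-rate units, where a
single spike in a 20 ms bin can exceed 2 baseline SDs: without it, an
isolated noise bin at t ≈ 0 hijacks the window and a true 0.5 s response
is reported as 20 ms. Activation latency is the mean over trials of the
first spike time inside the starting bin (trials without such a spike are
excluded; if none has one, the bin's start time is used and flagged);
suppression latency is the starting bin's start time, since absent spikes
have no timestamps. The response ends when the z-score returns across the
soft threshold for 2 consecutive bins — the hysteresis prevents a
single-bin dropout from truncating a response. The magnitude is the mean
z over the resulting window.

## Place-cell analysis

Tuning curves use 2 cm bins (95 on the default track), occupancy computed
from behavior samples with speed ≥ 2 cm/s, and the same movement filter on
spikes. The 2 cm/s threshold is reused from the decoding movement
criterion; occupancy for the spatial-information formula is the
movement-filtered time share.

Place fields are maximal circular runs of at least 3 bins above 5% of the
unit's peak rate, with the threshold crossings as the field limits and
multiple disjoint runs giving multiple fields. The 5% threshold is
unusually permissive, so two guards exist: a curve suprathreshold on every
occupied bin is rejected as non-specific, and the threshold is exposed in
the config. Field centers are rate-weighted circular means (wrap-safe).

A unit is a place cell iff it has at least one field on its
no-stimulation-lap tuning curve and its split-half tuning-curve Pearson
correlation is at least 0.3 and significant in *every* no-stimulation
epoch. The significance test is the two-sided correlation t-test at
α = 0.05 over the common occupied bins — the default test for a Pearson
coefficient.

Remapping is quantified by map correlations over bins occupied in both
curves (at least 10 common bins) and by circular distances of the dominant
field center from the puff location before and after stimulation, with
categories stable (shift ≤ 2 bins), remapped, vanished, emerged.

## Monosynaptic connectivity

Raw cross-correlograms use 1 ms bins over ±50 ms; lag bin b covers
(b − 0.5, b + 0.5] ms, so the "0–3 ms" monosynaptic window is exactly bins
1–3 and zero lag is its own excluded bin. The predictor convolves the raw
CCG with a Gaussian kernel (SD 10 ms — the convention of this predictor
approach; config-exposed) whose central bin is reduced by the hollow
fraction 0.6 and renormalized; near the window edges the truncated kernel
is renormalized so a flat CCG maps to itself exactly. A pair is connected
iff the global CCG peak falls in bins 1–3 and the observed count's Poisson
upper-tail probability under the predictor mean is below 0.001. No
multiple-testing correction is applied across pairs — the fixed P < 0.001
is the method's convention — so the empirical false-edge rate on
independent populations (about 2–4 per 1000 pairs in the calibration
suite) is the number to keep in mind at scale.

## Ripples, theta, phase precession

Ripples: zero-phase Butterworth band-pass 120–250 Hz, Hilbert envelope
(computed via the FFT analytic signal), thresholds in SD units of the
immobility-restricted envelope (mean + 1 SD sustained, peak above mean +
3 SD, ≥ 20 ms, fully within immobility). Immobility is speed < 2 cm/s
sustained ≥ 0.5 s — the mirror image of the movement criterion, since no
separate number is standard. Thresholding in SD units makes detection
invariant to amplitude scaling.

Theta phase comes from the 5–12 Hz analytic signal with the convention
0° = trough of the pyramidal-layer LFP; interneuron phase preferences
cluster near 0° under this convention. Phase at spike times interpolates
the analytic signal's real and imaginary parts (wrap-safe), not the
wrapped phase itself.

Phase precession is fit by circular–linear regression: the slope maximizes
the mean resultant length `R(a) = |mean exp(i(φ − a·x))|` over a bounded
range (±30 °/cm for place fields), on a dense grid with local refinement;
the offset is the circular mean of the residuals; start/stop phases come
from the linear model at the extremes of x. Significance uses 1000 phase
permutations of the same max-over-grid statistic (using the identical grid
for the observed and permuted statistics keeps the test exact). The
permutations are evaluated as one complex matrix product, so a fit with
hundreds of spikes takes well under a second.

## Assemblies

Pyramidal spiking is counted in 25 ms bins and z-scored per unit
(zero-variance units dropped). The number of co-activation components is
the count of correlation-matrix eigenvalues above the Marcenko–Pastur
upper edge. The asymptotic edge `(1 + √(n/B))²` is exceeded by the largest
eigenvalue of a genuinely uncorrelated population in a non-negligible
fraction of finite-size sessions — Tracy–Widom edge fluctuations — so the
default threshold is the finite-sample edge (Johnstone's largest-
eigenvalue law) at the 0.99 Tracy–Widom quantile; `tw_quantile = NULL`
restores the raw bound. Embedded-assembly eigenvalues in realistic regimes
sit far above either bound, so the correction affects the null rate, not
sensitivity.

Patterns come from a fixed-point symmetric ICA (cube nonlinearity,
deterministic seeded initialization, symmetric decorrelation, up to 5
seeded restarts) on the whitened projection onto the significant
components, back-projected to unit space, unit-normalized and sign-aligned
so the largest-magnitude weight is positive. Members are units whose
weight exceeds the pattern's mean + 2 SD (config-exposed; the method
itself defines no membership rule).

Reactivation strength is the quadratic form `R(t) = z(t)' P z(t)` with
`P = w w'` and the diagonal zeroed — the standard construction, which
guarantees single-unit firing alone cannot trigger a reactivation — with
events as local maxima above the raw threshold 5. The synthetic air-puff
template puts equal weights on the activated pyramidal cells
(`1/√n`, zero elsewhere); similarity is the absolute inner product, tested
against 1000 permutations of the pattern's weight entries at the 99th
percentile. When reactivation is evaluated on a restricted interval (e.g.
excluding air-puff laps), the z-scoring uses that interval's own mean and
SD.

## Bayesian decoding

Theta cycles are trough-to-trough intervals restricted to runs with speed
≥ 2 cm/s sustained ≥ 0.5 s, keeping durations within the 5–12 Hz period
range. Each cycle's population count vector is decoded with the Poisson
likelihood `P(x|n) ∝ Πᵢ fᵢ(x)^{nᵢ} exp(−τ Σᵢ fᵢ(x))` in the log domain,
with a uniform prior over training-occupied bins and a 0.01 Hz additive
rate floor inside the decoder only (zero-rate bins would otherwise
annihilate the posterior). The decoded position is the MAP bin; errors are
circular distances.

The error analysis follows the train/test scheme of the paradigm: maps
from the first half of a no-stimulation epoch decode its second half
(control), and maps from the second half decode the air-puff epoch.
Reward-zone analysis reports, per 2 cm bin of distance past the puff
location, the fraction of cycles whose MAP falls within ±20 cm of the
reward, against a null built from 1000 random control zones per cycle
(centers drawn uniformly, excluding the peri-reward zone and the cycle's
actual position); a bin is significant above the null's 97.5th percentile
— the upper tail of the conventional two-sided 5% logic, since the
question is one-sided but the band is reported two-sided. Reward-coding
cycles (within 3 s after a puff, MAP in the reward zone) rank pyramidal
cells by within-cycle firing rate into quintiles whose z-scored tuning
curves are averaged; quintile sizes differ by at most one unit.

## The synthetic-session generator

`generate_session()` draws a full session from an inhomogeneous Poisson
model, deterministic given its seed. What it emulates: the lap structure
(10-lap no-stimulation blocks alternating with air-puff blocks of one puff
per lap at 1–4 locations), constant-speed running (15 cm/s) with a 2 s
reward pause per lap (the immobility that carries ripples), circular
Gaussian place fields, theta modulation with linear phase precession
across the field, additive boxcar air-puff responses and multiplicative
suppression, pyramidal doublet bursts, spike transmission to interneurons
1–3 ms after presynaptic spikes, co-activation assemblies as shared
25 ms-aligned events, and an LFP with running theta and immobility ripple
bursts.

Defaults are the study conditions, chosen once:

* **10 trials per location** (top of the experimental 6–10 range): with
  20 ms bins, fewer trials let a single spike exceed 2 SD of a sub-1 Hz
  baseline, so detection would be dominated by count discreteness rather
  than by the response.
* **Air-puff locations L/n apart**, phased to maximize distance from the
  reward zone and kept off the lap-boundary wrap point. Track-spanning
  locations are what make the 2-of-3 consistency rule effective (see the
  response section).
* **Response kernel: additive 20 Hz boxcar**, latency 0.1 s, duration
  0.5 s. An additive step gives uniform detectability across baseline
  rates and matches the sharp burst responses this stimulus evokes;
  suppression is a ×0.1 rate factor for 1 s on an 8 Hz baseline (below
  ~1.7 Hz pooled baseline, z < −1 is unreachable and suppression is
  undetectable by any z-based rule).
* **Place cells**: field FWHM 15 cm (Gaussian SD ≈ 6.4 cm, i.e. ~30 cm
  fields at the 5% threshold), peak 12 Hz, out-of-field rate 0.1× the
  drawn baseline — real place cells are close to silent out of field, and
  a uniform sub-threshold floor is what makes the 5%-of-peak rule
  meaningful.
* **Baselines**: lognormal, median 0.8 Hz (pyramidal) and 10 Hz
  (interneurons); pyramidal doublet-burst probability 0.3 at 4–8 ms,
  which drives the burst-index classifier.
* **Assemblies**: 0.2 Hz shared activation events multiplying member
  activity within one aligned 25 ms window (~2 extra spikes per member);
  **connections**: transmission probability 0.1 at 1.5 ± 0.3 ms.

What it does not emulate: speed variability and behavioral state changes,
overdispersed (non-Poisson) slow rate fluctuations, waveform-level
artifacts, electrode drift, inhibitory suppression of the LFP, or
cross-frequency coupling. Passing recovery tests on this generator
therefore shows the estimators are correct under the stated statistical
model, not that real-data preprocessing is robust to everything real
recordings contain.

Two switches inject the structural effects studied with decoding: a
localized post-puff remap (fields evaluated at a shifted position inside a
35 cm segment after the puff, only on air-puff laps) and reward
reactivation (reward-proximal place cells gain an additive rate boost for
3 s after each puff). They exist so the decoding-error confinement and the
reward-zone probability shift can be tested as recoveries with known
ground truth.

## Problem sizes and determinism

The test and acceptance suites run at desk scale, chosen to finish in a
few minutes on one CPU: 25–50 units per synthetic session, 5–45 laps,
50-seed null calibrations, 1000 simulated pairs for the connectivity null,
500 draws for the template-similarity calibration, 10 seeds for assembly
recovery, and single sessions for the decoding analyses. All stochastic
stages take explicit seeds (generator, ICA, permutation and Monte-Carlo
tests), and the pipeline writes byte-identical artifacts for identical
(session, config, seed).

## Known limitations

* Suppression detection needs a pooled baseline expectation above ~1.7 Hz;
  genuinely suppressed low-rate cells are invisible to any z < −1
  criterion at these bin sizes and trial counts.
* The per-location consistency rule assumes stimulus locations are farther
  apart than the response window's track span; paradigms with closely
  spaced locations will let place-locked artifacts through.
* The connectivity test controls the per-pair error rate only; large
  populations need an external error-rate argument (or a stricter α).
* Ripple detection is envelope-based and reports no spectral features.
* The decoder assumes Poisson spiking and independence across units; both
  are violated by bursting and co-activation, which inflates posterior
  confidence more than it shifts the MAP.
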