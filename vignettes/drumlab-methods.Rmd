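---
title: "From raw drumming signals to mixed-model inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw drumming signals to mixed-model inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumlab)
```

## The experiment drumlab models

drumlab implements the complete measurement and inference chain for a
music-playing psychophysiology experiment: participants drum along to piano
accompaniment under a 2×2 crossover of *playing condition* (Improvise vs.
maintaining the Beat) and *accompaniment* (Live vs. Recorded), across four
composition styles (March, Waltz, Salsa, Rock), giving 16 one-minute playing
trials per subject plus one listen-only baseline trial. Per trial the
pipeline reduces six raw modalities to a single row of outcome measures:

* **Mean EMG peak activation (%MVC)** — how hard the wrist muscles work per
  movement, independent of how often the participant strikes.
* **Total acceleration** — cumulative hand movement over the whole trial.
* **Drum strike count** — discrete count of taps, from the MIDI stream.
* **Tonic EDA change (µS)** — sympathetic arousal relative to the subject's
  listen-only baseline.
* **BPM and RMSSD (ms)** — mean heart rate and beat-to-beat variability from
  the ECG.
* **Reward and challenge scores** — the first two principal components of a
  12-item Likert experience survey.

These feed linear mixed models with a subject random intercept that test the
condition effects and, in a second family of models, whether the
reward–movement association is specific to improvisation.

## Signal processing

### EMG

Raw EMG (2000 Hz, mV) is band-passed 10–400 Hz by cascading a 2nd-order
high-pass and a 3rd-order low-pass Butterworth filter, then rectified as the
RMS over contiguous 10 ms windows and divided by the subject's maximum
voluntary contraction (MVC), defined as the largest mean over any one-second
window of the rectified MVC calibration trace.

All offline filters are applied forward–backward (zero phase). The
magnitude response is therefore the *squared* cascade response, and peak
timing is undistorted — which matters because movement-related EMG peaks are
identified by alignment with accelerometer Z peaks (±100 ms tolerance,
configurable). Tests verify the realized gain against the closed-form
digital Butterworth magnitude response (the analog prototype at the
bilinear-prewarped frequency `tan(πf/fs)`), to 1% across the band.

Within each trial the lowest 10% of matched EMG peak amplitudes
(`floor(0.10·n)`, ties broken by dropping the earliest-time tied peak) are
discarded as noise, the remaining amplitudes are averaged, and the flexor
and extensor means are averaged into a single per-trial value. The drop is
applied per muscle before averaging; the alternative (averaging envelopes
first) is noted but not used.

### Accelerometry

All axes are brought to a common 250 Hz grid (integer-ratio decimation with
zero-phase Chebyshev anti-aliasing via `signal::decimate`; an axis already
at 250 Hz — the legacy y-axis case — passes through). Gravity is removed
with a 4th-order 0.5 Hz high-pass Butterworth, again zero-phase; each axis
is demeaned first so the forward–backward edge transient is negligible. One
second is trimmed from each end (≈3.3% of a 60 s trial, well under the 10%
loss bound, which is enforced). Magnitude is `√(x²+y²+z²)` and **total
acceleration** is its plain sum (units g·samples at 250 Hz).

Strike-related Z peaks are local maxima of |z| above `median + k·MAD`. The
threshold default is k = 8: on Gaussian sensor noise, |z| is half-normal and
5 scaled MADs sits near 3.2σ, which fires spuriously on a motionless
minute, whereas 8 MADs (≈5σ) yields an empty peak set unless genuine
transients are present. Peaks closer than 150 ms collapse to the larger.

### ECG

The trace is detrended (least-squares linear trend by default; order-2
polynomial available) and candidate local maxima are found (strictly greater
than both neighbors; plateaus take their first sample). Candidates below 40%
of the global post-detrend maximum are discarded — this automates the visual
rejection of between-beat noise maxima, which the literal windowed rule
cannot eliminate at slow heart rates (below 60 BPM a 1 s window centered
between beats may contain no R wave at all). Then, within a 1 s window
centered on each candidate, candidates below 80% of the window maximum are
removed, and survivors within 250 ms collapse to the single largest (guards
double-counting on broad QRS complexes).

From the R-wave series, `BPM = fs / mean(Δindex) × 60` and RMSSD is the
root mean square of successive differences of the inter-beat intervals in
milliseconds.

### EDA

Tonic level is the arithmetic mean of the one-minute trace (no phasic/tonic
decomposition), baselined by subtracting the same subject's listen-only
tonic level; the difference may be negative, and a missing baseline
propagates as an explicit missing value.

### Automated quality control

Visual-inspection exclusions are replaced by flags: `eda_ceiling` (≥5% of
samples within 1% of the trace maximum — saturation), `eda_flat` (variance
below floor), and `ecg_low_snr` (99.9th-percentile amplitude over robust
MAD noise below 8 after detrending). A flag excludes the trial from the
*corresponding outcome only*; every exclusion is recorded in a QC log with
trial identity and reason.

## Survey reduction

The 12 Likert items are reduced by PCA on the item **correlation** matrix
(items share the 1–5 scale but differ in variance; the choice is recorded
here because either matrix is defensible). No rotation is applied. The
retained component count comes from parallel analysis: observed eigenvalues
are compared with the 95th percentile of eigenvalues from 1000
standard-normal matrices of the same shape, retaining components while each
successive observed eigenvalue exceeds its reference. At the 95th
percentile, the chance of retaining any component from pure noise stays
near 5%.

Component signs are arbitrary, so they are anchored: the first component is
oriented so the *pleasure* item loads positively and labelled **reward**;
the second so *difficulty* loads positively, labelled **challenge**.
Trials (480 rows), not subjects, are the PCA rows; within-subject
dependence is handled downstream by the mixed models, not here. Scores are
standardized to unit variance per component. The synchrony item both
participates in the PCA and is analyzed separately as its own outcome.
Items enter raw (no per-subject standardization).

## Mixed-model inference

Each outcome is modelled as

```
outcome ~ playing * accompaniment + style + BMRQ + Gold-MSI + (1 | subject)
```

by REML (`lme4`), with treatment contrasts referenced at Beat / Recorded /
March. For the autonomic outcomes (tonic EDA, BPM, RMSSD) total
acceleration is additionally required as a covariate, so motion cannot
explain autonomic effects. Fixed effects are tested with Type II Wald
chi-squares (`car::Anova`) — Type II because main effects should be judged
without their own interactions when an interaction term is present.
Continuous covariates are standardized internally for numerical stability;
simple slopes are back-transformed to per-original-unit values for
reporting.

Marginal means of the four condition cells are averaged over style with
covariates at their means (`emmeans`), and all six pairwise differences are
Tukey-adjusted. Moderation models add a motor measure and its three-way
interaction with the two condition factors; per-condition simple slopes of
reward on the motor measure carry 95% CIs, the slope difference is tested
directly, and the moderation p-value is additionally Bonferroni-adjusted
across the three motor measures (×3). Degrees of freedom for follow-up
contrasts use the Satterthwaite method by default (asymptotic available for
simulation loops); the method used is recorded in the fit metadata rather
than matched to any particular convention.

QC-excluded trials are dropped listwise per outcome, so each outcome's n
reflects its own exclusions.

## The synthetic-study generator

No human recordings ship with the package; a generator produces complete
studies with the statistical structure the analysis assumes, at two levels.

**Measures level** (`simulate_measures()`): per-trial outcomes are drawn
directly from the linear model — condition effects (in residual-SD units) +
a subject random intercept (SD 1) + residual (SD 1) — and mapped onto each
measure's physical scale. The default effects encode the qualitative study
conditions: an Improvise×Live interaction on reward, total acceleration and
EMG; an Improvise main effect on strike count, challenge and the autonomic
outcomes; style differences with March lowest; a BMRQ slope on reward; and
a reward–motor coupling of 0.30 (standardized scale) in Improvise trials
only, with zero coupling under Beat. These values were fixed once, from the
direction and approximate standardized magnitude of the reported effects in
this literature, and are the conditions under which the package's
operating-characteristic checks (type-I error, power, coverage) run. This
level drives the inference simulations, where hundreds of replicates make
raw-signal synthesis pointless.

**Signal level** (`simulate_study()` + `simulate_trial_signals()`): the same
latent draws become synthesis targets for raw traces:

* *Strikes*: exactly n events per trial on a jittered grid (σ = 20 ms) for
  Beat; for Improvise the grid is smoothly time-warped (bounded-derivative
  monotone warp), capturing rate variation without modelling musical
  structure. MIDI note-ons are written at the strike times.
* *EMG*: a 100 Hz carrier under a 150 ms Hann window at each strike, scaled
  so the normalized envelope peak equals the planted %MVC amplitude;
  per-subject MVC calibration traces contain a 1.4 s plateau encoding the
  MVC constant.
* *Accelerometry*: 1 g gravity on z plus 60 ms raised-cosine transients at
  strike times (x/y at 30% amplitude); the first 14 subjects' y axis is
  produced at 250 Hz, emulating the legacy acquisition case.
* *ECG*: a QRS train with 80 ms raised-cosine support, exponentiated
  (power 6) so the apex is sharp enough for sample-accurate localization —
  a real R wave's steep upstroke, which a plain 80 ms raised cosine lacks.
  Baseline noise defaults to 0.2% of R amplitude for the same reason; the
  low-SNR QC scenario covers noisy regimes explicitly. Inter-beat intervals
  are recentered and rescaled so the realized mean and RMSSD equal the
  programmed values *exactly*; closed-loop tolerances therefore test the
  detector, not sampling error. Infeasible programs (RMSSD implying
  non-physiological intervals) are rejected.
* *EDA*: tonic level plus a slow sinusoidal drift and small noise, at
  250 Hz (the acquisition rate for EDA is immaterial to a trial mean; 250 Hz
  keeps files small). The ceiling scenario clips the trace at its 85th
  percentile.
* *Surveys*: items are `3 + loadings · latent + noise`, rounded and clamped
  to 1–5. Discretization loses information; the loading-recovery tests
  accept Tucker congruence ≥ 0.9 rather than exactness.

Per-trial seeds derive from the study seed, so signals regenerate lazily
and deterministically; a written dataset is byte-identical across runs of
the same seed.

### What the generator does not emulate

Real EMG interference patterns, motion artifacts in EDA, ectopic beats and
T waves in ECG, musical structure in strike timing, and item response
styles in surveys are all absent. Passing closed-loop tests therefore shows
that the pipeline's arithmetic and detection logic are correct under the
assumed signal model — not that the pipeline is robust to every artifact of
human data. The QC scenarios (EDA ceiling, low-SNR ECG) exercise the
exclusion mechanism, not the full space of real-world failure.

## Numerical choices and degenerate inputs

* Half-open trial windows `[start, end)` everywhere; envelope timestamps at
  window centers; trailing partial RMS windows dropped.
* MIDI note-on with velocity 0 is treated as note-off (running-status
  dialect); only velocity > 0 onsets count. Chords count once per event.
* Measures tables serialize doubles at 17 significant digits and are parsed
  with the correctly-rounded base parser, making write→read bit-exact.
* Empty peak/beat sets raise errors or explicit flagged missings — never
  silent zeros. Constant (degenerate) covariates are rejected by the model
  layer; singular random-effect fits are flagged, not fatal.
* Tie-breaks: trim drops the earliest-time tied peak; plateau maxima take
  the first sample; simultaneous MIDI events each count.

## Problem sizes used in the test suite

The suite exercises the full 30-subject design where the quantity under
test needs it (parallel-analysis retention rates, power at the planted
1-SD interaction, simple-slope coverage at the default coupling of 0.30)
and smaller designs elsewhere: 2-subject studies for end-to-end signal
checks, 12-subject null replicates (500 of them) for the type-I error of
the interaction Wald test, and 10 seeded trials per setting for the
closed-loop physiology grids (heart rate 55/70/90 BPM × RMSSD 5/20/50 ms).
Parallel-analysis rate checks use 500 reference matrices per replicate
(the analysis default is 1000).

## Known limitations

* The Wald chi-square is asymptotic; with 30 subjects its type-I error is
  near nominal (verified by simulation) but small-sample df corrections
  (Kenward–Roger) are not used for the omnibus tests.
* Parallel analysis uses normal reference data, not resampled Likert
  margins; with 12 items and 480 trials the difference is small.
* The movement-peak matcher takes the envelope maximum within the
  tolerance window; overlapping windows at very high strike rates could
  double-match and are resolved by dropping duplicates into the QC count.
* Flexor and extensor are never reported separately, and no spectral/fatigue
  EMG analysis, frequency-domain HRV, or phasic EDA decomposition is
  provided — these are out of scope by design.
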