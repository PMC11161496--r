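# drumlab

Psychophysiology experiments on music playing ask a deceptively simple
question: does *how* people make music — improvising versus keeping a beat,
playing with a live partner versus a recording — change how much they move,
how aroused they are, and how rewarding the playing feels? Answering it
requires reducing six raw recording modalities to per-trial outcome
measures and then fitting within-subject mixed models. drumlab implements
that entire chain as a tested, reusable R package, together with a
synthetic-study generator so every stage can be verified without human
data.

It is written for researchers in music cognition, motor rehabilitation and
psychophysiology who run (or reanalyze) drumming/tapping paradigms with
biosignal recordings, and for methodologists who want a fully simulatable
testbed for this class of pipeline.

## What it computes

For each one-minute playing trial of a 2×2 crossover (playing condition
Improvise/Beat × accompaniment Live/Recorded, across four composition
styles, 16 trials per subject plus a listen-only baseline):

| Measure | Definition |
|---|---|
| Mean EMG peak activation | EMG band-passed 10–400 Hz (2nd-order HP ∘ 3rd-order LP Butterworth, zero phase), RMS-rectified over 10 ms windows, normalized by MVC (max 1-s window mean of the calibration trace); movement peaks aligned to accelerometer Z peaks (±100 ms), lowest 10% dropped, remainder averaged, flexor and extensor averaged |
| Total acceleration | axes resampled to 250 Hz, 4th-order 0.5 Hz high-pass removes gravity, Σ√(x²+y²+z²) |
| Drum strike count | MIDI note-ons (velocity > 0) in the half-open trial window |
| Tonic EDA change | trial mean minus the subject's listen-only mean (µS) |
| BPM | `fs / mean(samples per beat) × 60` from detected R waves |
| RMSSD | √mean(ΔIBI²) in ms (heart-rate variability) |
| Reward, challenge | first two principal components of the 12-item experience survey (correlation matrix, component count by parallel analysis, signs anchored at the pleasure/difficulty items) |

Inference: per-outcome linear mixed models
`outcome ~ playing × accompaniment + style + BMRQ + Gold-MSI + (1 | subject)`
(total acceleration added as covariate for autonomic outcomes), Type II
Wald χ² tests, Tukey-adjusted pairwise contrasts of the four condition
cells averaged over style, and moderation models testing whether the
reward–movement slope is specific to improvisation (per-condition simple
slopes with 95% CIs, Bonferroni across the three motor measures).

## Worked example

```r
library(drumlab)

study    <- simulate_study(sim_config(n_subjects = 4), seed = 7)
study
#> <drum_study: 4 subjects, 64 playing trials + 4 listen-only, seed 7>

measures <- derive_measures(study, pa_seed = 8)
dplyr::select(measures[1:4, ], trial_id, playing_condition, accompaniment,
              mean_emg_pct_mvc, strike_count, bpm, rmssd)
#> # A tibble: 4 × 7
#>   trial_id playing_condition accompaniment mean_emg_pct_mvc strike_count   bpm
#> 1 S01_T01  Improvise         Live                     0.417           83  84.2
#> 2 S01_T02  Improvise         Recorded                 0.352          120  78.8
#> 3 S01_T03  Beat              Live                     0.347          101  76.8
#> 4 S01_T04  Beat              Recorded                 0.278           88  79.4

attr(measures, "component_model")
#> <component_model: 2 component(s) (reward, challenge), variance 35.6% / 24.5%>

fit <- fit_condition_model(measures, "strike_count")
tidy(fit)
#> # A tibble: 6 × 4
#>   term           chisq    df        p
#> 1 playing       10.7       1 1.08e- 3
#> ...
```

Reading the output: each derived row carries the trial's motor, autonomic
and survey measures (here EMG activation is a fraction of MVC — 0.417 means
41.7% of maximum voluntary contraction). Parallel analysis retained two
survey components, oriented and labelled reward and challenge. The Wald
table shows a playing-condition effect on strike count (χ² = 10.7,
p ≈ 0.001): this tiny 4-subject demo already reflects the generator's
planted Improvise effect on strike rate. `pairwise_contrasts(fit)` gives
the six Tukey-adjusted cell contrasts and `fit_moderation_model()` +
`simple_slopes()` the reward–motor coupling analysis.

Raw-data formats are fully supported in both directions: `write_study()`
materializes a dataset as CSV signal tables with JSON sidecar schemas,
Standard MIDI Files and survey/participant/manifest CSVs, and
`read_study()` / `derive_measures()` run the identical pipeline from disk.

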