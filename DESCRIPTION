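Package: drumlab
Title: Multimodal Signal Processing and Mixed-Model Inference for Drum-Playing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for psychophysiology experiments on
    music playing. Derives per-trial outcome measures from raw recordings:
    wrist flexor/extensor electromyography (band-pass filtering, RMS
    rectification, normalization to maximum voluntary contraction, and
    movement-peak averaging aligned to accelerometry), triaxial accelerometry
    (gravity removal and total acceleration), drum strike counts from Standard
    MIDI Files, tonic electrodermal activity with listen-only baselining, and
    electrocardiography (R-wave detection, heart rate, and RMSSD heart-rate
    variability). Reduces a 12-item Likert experience survey to principal
    components retained by parallel analysis, and fits linear mixed models
    with Wald chi-square tests, Tukey-adjusted marginal contrasts, and
    simple-slope moderation analyses. Includes a synthetic-study generator
    emulating a 2x2 crossover drumming experiment so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    signal,
    zoo,
    lme4,
    car,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
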