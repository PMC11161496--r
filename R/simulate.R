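# Synthetic-study generator. Emulates a 2x2 crossover drumming experiment:
# 30 subjects x 16 one-minute playing trials (Improvise/Beat x Live/Recorded
# across four composition styles) plus one listen-only EDA baseline trial per
# subject. Two levels are provided: simulate_measures() draws the per-trial
# outcome table directly from the statistical model (used for inference
# simulations), while simulate_study()/simulate_trial_signals() synthesize
# raw traces (EMG bursts, accelerometer transients, a QRS template train,
# tonic EDA, MIDI note-ons) so the whole signal pipeline can be exercised
# closed loop.

# Run code under a temporary RNG state so lazy per-trial generation is
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

OUTCOMES <- c("pc_reward", "pc_challenge", "total_acceleration",
              "mean_emg_pct_mvc", "strike_count", "tonic_eda_delta",
              "bpm", "rmssd")

style_vec <- function(march = 0, waltz = 0, salsa = 0, rock = 0)
  c(March = march, Waltz = waltz, Salsa = salsa, Rock = rock)

one_effect <- function(playing = 0, accomp = 0, interaction = 0,
                       style = style_vec(), bmrq = 0)
  list(playing = playing, accomp = accomp, interaction = interaction,
       style = style, bmrq = bmrq)

#' Default and null condition-effect sets for the generator
#'
#' Effects are expressed in residual-SD units of each outcome's latent scale.
#' The defaults encode the qualitative study conditions: an
#' Improvise-by-Live interaction on reward, total acceleration and EMG; an
#' Improvise main effect on strike count, challenge and the autonomic
#' outcomes; composition-style differences with March lowest; and a
#' reward-sensitivity (BMRQ) slope on reward.
#'
#' @return Named list of per-outcome effect lists.
#' @export
default_effects <- function() list(
  pc_reward = one_effect(playing = 0.4, accomp = 0.25, interaction = 0.5,
                         style = style_vec(0, 0.20, 0.35, 0.45), bmrq = 0.2),
  pc_challenge = one_effect(playing = 0.9,
                            style = style_vec(0, 0.10, 0.15, 0.15)),
  total_acceleration = one_effect(playing = 0.15, interaction = 0.45,
                                  style = style_vec(0, 0.30, 0.35, 0.40)),
  mean_emg_pct_mvc = one_effect(playing = 0.5, interaction = 0.35,
                                style = style_vec(0, 0.25, 0.45, 0.55)),
  strike_count = one_effect(playing = 0.7,
                            style = style_vec(0, 0.20, 0.25, 0.30),
                            bmrq = 0.15),
  tonic_eda_delta = one_effect(playing = 0.35,
                               style = style_vec(0, 0.10, 0.15, 0.15)),
  bpm = one_effect(playing = 0.6, style = style_vec(0, 0.05, 0.10, 0.10)),
  rmssd = one_effect(playing = -0.35)
)

#' @rdname default_effects
#' @export
null_effects <- function() setNames(lapply(OUTCOMES, function(o) one_effect()),
                                    OUTCOMES)

#' Configuration of the synthetic study
#'
#' Collects every tunable of the generator. The defaults are the study
#' conditions: 30 subjects, 16 one-minute playing trials in a 2x2 crossover
#' over four composition styles plus a listen-only baseline trial, 2000 Hz
#' EMG/ECG/accelerometry (with the 250 Hz legacy y axis for the first 14
#' subjects), and the effect sizes of [default_effects()].
#'
#' @param n_subjects Number of subjects.
#' @param trial_s Trial duration, seconds.
#' @param fs Raw sampling rate for EMG/ECG/accelerometry, Hz.
#' @param fs_eda EDA sampling rate, Hz.
#' @param n_legacy_y_subjects Number of leading subjects whose accelerometer
#'   y axis is sampled at 250 Hz.
#' @param style_tempo Strike tempo per style for the Beat condition,
#'   strikes/minute.
#' @param effects Per-outcome condition effects (see [default_effects()]).
#' @param subject_sd,resid_sd Random-intercept and residual SDs on the latent
#'   scale.
#' @param coupling Reward-motor coupling: list with `motor` (the measure) and
#'   `slope` (named per playing condition, on the standardized-motor scale).
#' @param survey_loadings 12 x 2 item loading matrix for survey synthesis.
#' @param survey_noise_sd Item noise SD before Likert discretization.
#' @param emg,accel,ecg,eda Signal-synthesis parameter lists (amplitudes,
#'   noise levels, template widths); see the methods vignette.
#' @param qc_scenarios List of trial-id vectors for injected artifacts:
#'   `eda_ceiling` (clipped EDA) and `ecg_low_snr` (noise at QRS amplitude).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 30, trial_s = 60, fs = 2000, fs_eda = 250,
                       n_legacy_y_subjects = 14,
                       style_tempo = c(March = 100, Waltz = 90,
                                       Salsa = 110, Rock = 120),
                       effects = default_effects(),
                       subject_sd = 1, resid_sd = 1,
                       coupling = list(motor = "total_acceleration",
                                       slope = c(Beat = 0, Improvise = 0.3)),
                       survey_loadings = default_survey_loadings(),
                       survey_noise_sd = 0.5,
                       emg = list(mvc_mv = c(flexor = 1.2, extensor = 0.9),
                                  base_frac = 0.30, amp_log_scale = 0.15,
                                  burst_ms = 150, carrier_hz = 100,
                                  noise_mv = 0.01),
                       accel = list(base_amp_g = 1.5, amp_log_scale = 0.25,
                                    pulse_ms = 60, xy_frac = 0.3,
                                    noise_g = 0.01),
                       ecg = list(base_hr = 75, hr_scale = 6,
                                  base_rmssd = 30, rmssd_log_scale = 0.25,
                                  amp_mv = 1, noise_mv = 0.002,
                                  r_sharpness = 6),
                       eda = list(base_us = 5, subject_sd_us = 1.5,
                                  delta_scale_us = 0.4, drift_us = 0.2,
                                  noise_us = 0.01),
                       strike_scale = 20,
                       qc_scenarios = list(eda_ceiling = character(0),
                                           ecg_low_snr = character(0))) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, trial_s > 0, fs > 0,
            all(unlist(style_tempo) > 0))
  class(cfg) <- "sim_config"
  cfg
}

# Balanced condition orders (one row per randomized order group); columns are
# the four playing x accompaniment cells.
CONDITION_CELLS <- data.frame(
  playing_condition = rep(PLAYING_LEVELS, each = 2),
  accompaniment = rep(ACCOMP_LEVELS, 2),
  stringsAsFactors = FALSE
)
CONDITION_ORDERS <- rbind(c(1, 2, 3, 4), c(2, 4, 1, 3),
                          c(3, 1, 4, 2), c(4, 3, 2, 1))

sim_participants <- function(cfg) {
  n <- cfg$n_subjects
  tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    bmrq_total = pmin(100, pmax(65, round(rnorm(n, 85, 9)))),
    gold_msi_training = pmin(49, pmax(7, round(rnorm(n, 25.4, 10.8))))
  )
}

sim_manifest <- function(cfg, participants) {
  rows <- map_dfr(seq_len(cfg$n_subjects), function(i) {
    ord <- CONDITION_ORDERS[sample.int(4, 1), ]
    style_order <- sample(STYLE_LEVELS)
    play <- map_dfr(seq_along(style_order), function(b) {
      cells <- CONDITION_CELLS[ord, ]
      cells$style <- style_order[b]
      cells$order_position <- (b - 1L) * 4L + seq_len(4L)
      cells
    })
    play$subject_id <- participants$subject_id[i]
    play$is_listen_only <- FALSE
    listen <- tibble(subject_id = participants$subject_id[i],
                     playing_condition = NA_character_,
                     accompaniment = NA_character_,
                     style = NA_character_, order_position = 0L,
                     is_listen_only = TRUE)
    bind_rows(listen, play)
  })
  rows |>
    mutate(trial_id = ifelse(.data$is_listen_only,
                             paste0(.data$subject_id, "_listen"),
                             sprintf("%s_T%02d", .data$subject_id,
                                     .data$order_position)),
           .before = 1)
}

# Latent per-trial outcome draws: condition effects + subject intercept +
# residual, in residual-SD units.
sim_latents <- function(cfg, manifest, participants) {
  play <- manifest[!manifest$is_listen_only, ]
  n <- nrow(play)
  bmrq_z <- if (nrow(participants) > 1 && sd(participants$bmrq_total) > 0)
    as.numeric(scale(participants$bmrq_total)) else rep(0, nrow(participants))
  names(bmrq_z) <- participants$subject_id
  out <- play
  for (oc in OUTCOMES) {
    ef <- cfg$effects[[oc]]
    u <- rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    names(u) <- participants$subject_id
    eta <- ef$playing * (play$playing_condition == "Improvise") +
      ef$accomp * (play$accompaniment == "Live") +
      ef$interaction * (play$playing_condition == "Improvise" &
                          play$accompaniment == "Live") +
      unname(ef$style[play$style]) +
      ef$bmrq * bmrq_z[play$subject_id] +
      u[play$subject_id] +
      rnorm(n, 0, cfg$resid_sd)
    out[[paste0("eta_", oc)]] <- unname(eta)
  }
  out
}

# Map latent draws to physical measure scales.
latents_to_measures <- function(cfg, lat) {
  tempo <- unname(cfg$style_tempo[as.character(lat$style)])
  m <- lat |>
    mutate(
      total_acceleration = 400 + 60 * .data$eta_total_acceleration,
      mean_emg_pct_mvc = cfg$emg$base_frac *
        exp(cfg$emg$amp_log_scale * .data$eta_mean_emg_pct_mvc),
      strike_count = pmin(150L, pmax(1L, as.integer(round(
        tempo + cfg$strike_scale * .data$eta_strike_count)))),
      tonic_eda_delta = cfg$eda$delta_scale_us * .data$eta_tonic_eda_delta,
      bpm = cfg$ecg$base_hr + cfg$ecg$hr_scale * .data$eta_bpm,
      rmssd = cfg$ecg$base_rmssd *
        exp(cfg$ecg$rmssd_log_scale * .data$eta_rmssd)
    )
  # reward-motor coupling on the standardized-motor scale, per playing cond.
  motor_z <- as.numeric(scale(m[[cfg$coupling$motor]]))
  slope <- cfg$coupling$slope[as.character(m$playing_condition)]
  m$pc_reward <- m$eta_pc_reward + unname(slope) * motor_z
  m$pc_challenge <- m$eta_pc_challenge
  m
}

#' Simulate a per-trial measures table directly
#'
#' Draws the measures table from the generator's statistical model without
#' synthesizing raw signals: per-trial outcomes are condition effects plus a
#' subject random intercept plus residual noise, mapped onto each measure's
#' physical scale, with the reward-motor coupling applied per playing
#' condition. This is the generator used for type-I-error, power and coverage
#' simulations of the inference layer.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble with one row per playing trial: identifiers, conditions,
#'   participant covariates and all outcome columns.
#' @export
simulate_measures <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    participants <- sim_participants(config)
    manifest <- sim_manifest(config, participants)
    lat <- sim_latents(config, manifest, participants)
    m <- latents_to_measures(config, lat)
    syn <- pmin(5, pmax(1, round(3.5 + 0.4 * m$eta_pc_reward)))
    m$synchrony_rating <- as.integer(syn)
    m |>
      left_join(participants, by = "subject_id") |>
      select("trial_id", "subject_id", "playing_condition", "accompaniment",
             "style", "order_position", "bmrq_total", "gold_msi_training",
             dplyr::all_of(OUTCOMES), "synchrony_rating")
  })
}

#' Default survey loading structure
#'
#' Two latent dimensions: reward loads positively on pleasure, motivation,
#' activation, momentum, creativity, activity and absorption; challenge loads
#' positively on difficulty, fatigue and surprise and negatively on
#' familiarity and synchrony.
#'
#' @return 12 x 2 matrix, rows per [survey_items].
#' @export
default_survey_loadings <- function() {
  L <- matrix(0, nrow = 12, ncol = 2,
              dimnames = list(survey_items, c("reward", "challenge")))
  L[c("pleasure", "motivation", "activation", "momentum",
      "creativity", "activity", "absorption"), "reward"] <-
    c(0.75, 0.70, 0.65, 0.65, 0.60, 0.60, 0.55)
  L[c("difficulty", "fatigue", "surprise"), "challenge"] <- c(0.70, 0.65, 0.60)
  L[c("familiarity", "synchrony"), "challenge"] <- c(-0.55, -0.50)
  L
}

#' Simulate Likert survey responses from latent scores
#'
#' Items are a linear combination of the latent reward/challenge scores plus
#' Gaussian noise, centered on the scale midpoint and discretized to 1-5 by
#' rounding with clamping.
#'
#' @param latents n x 2 matrix (reward, challenge) of latent trial scores.
#' @param loadings 12 x 2 loading matrix.
#' @param noise_sd Item noise SD.
#' @param seed Optional integer seed.
#' @return n x 12 integer matrix with columns [survey_items].
#' @export
simulate_survey <- function(latents, loadings = default_survey_loadings(),
                            noise_sd = 0.5, seed = NULL) {
  latents <- as.matrix(latents)
  run <- function() {
    raw <- 3 + latents %*% t(loadings) +
      matrix(rnorm(nrow(latents) * nrow(loadings), 0, noise_sd),
             nrow(latents))
    items <- pmin(pmax(round(raw), 1L), 5L)
    storage.mode(items) <- "integer"
    colnames(items) <- rownames(loadings)
    items
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete synthetic study
#'
#' Lays out the crossover design (randomized condition order repeated over a
#' randomized composition-block order), draws participant covariates and
#' per-trial latent outcomes, converts them to physical signal-synthesis
#' targets and survey responses, and assigns each trial a derived seed so raw
#' signals can be generated lazily and reproducibly by
#' [simulate_trial_signals()]. Use [write_study()] to materialize the dataset
#' on disk in the formats the readers consume.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A `drum_study` object: `participants`, `manifest`, `trials`
#'   (per-trial synthesis targets), `surveys`, `mvc` (per-subject MVC
#'   targets), `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    participants <- sim_participants(config)
    manifest <- sim_manifest(config, participants)
    lat <- sim_latents(config, manifest, participants)
    m <- latents_to_measures(config, lat)

    # standardized latents feed the survey; coupling already in pc_reward
    latmat <- cbind(reward = as.numeric(scale(m$pc_reward)),
                    challenge = as.numeric(scale(m$pc_challenge)))
    items <- simulate_survey(latmat, config$survey_loadings,
                             config$survey_noise_sd)
    surveys <- bind_cols(
      m |> select("trial_id", "subject_id"),
      as_tibble(items)
    )

    mvc <- tibble(
      subject_id = participants$subject_id,
      flexor = config$emg$mvc_mv[["flexor"]] * exp(rnorm(config$n_subjects, 0, 0.15)),
      extensor = config$emg$mvc_mv[["extensor"]] * exp(rnorm(config$n_subjects, 0, 0.15)),
      seed = sample.int(2^30, config$n_subjects)
    )

    eda_baseline <- tibble(
      subject_id = participants$subject_id,
      eda_level = pmax(1, config$eda$base_us +
                         config$eda$subject_sd_us * rnorm(config$n_subjects)),
      hr_rest = config$ecg$base_hr - 3 + 2 * rnorm(config$n_subjects),
      rmssd_rest = config$ecg$base_rmssd * exp(rnorm(config$n_subjects, 0, 0.2))
    )

    trials <- m |>
      left_join(eda_baseline, by = "subject_id") |>
      mutate(
        accel_amp_g = config$accel$base_amp_g *
          exp(config$accel$amp_log_scale *
                (.data$eta_total_acceleration - mean(.data$eta_total_acceleration)) /
                sd(.data$eta_total_acceleration)),
        eda_trial_level = .data$eda_level + .data$tonic_eda_delta,
        trial_seed = sample.int(2^30, dplyr::n())
      ) |>
      select("trial_id", "subject_id", "playing_condition", "accompaniment",
             "style", "order_position",
             "strike_count", "mean_emg_pct_mvc", "accel_amp_g",
             "bpm", "rmssd", "eda_trial_level", "eda_level",
             "tonic_eda_delta", "pc_reward", "pc_challenge", "trial_seed",
             "synchrony_rating" = "eta_pc_reward") |>
      mutate(synchrony_rating = as.integer(
        pmin(5, pmax(1, round(3.5 + 0.4 * .data$synchrony_rating)))))

    listen <- manifest |>
      filter(.data$is_listen_only) |>
      left_join(eda_baseline, by = "subject_id") |>
      mutate(trial_seed = sample.int(2^30, dplyr::n()))

    structure(
      list(config = config, seed = seed, participants = participants,
           manifest = manifest, trials = trials, listen = listen,
           surveys = surveys, mvc = mvc, dir = NULL),
      class = "drum_study")
  })
}

#' @export
print.drum_study <- function(x, ...) {
  cat(sprintf("<drum_study: %d subjects, %d playing trials + %d listen-only, seed %d%s>\n",
              nrow(x$participants), nrow(x$trials), nrow(x$listen), x$seed,
              if (is.null(x$dir)) "" else paste0(", on disk at ", x$dir)))
  invisible(x)
}

# ---- raw signal synthesis ---------------------------------------------------

# n strike times over the trial: an evenly spaced grid, jittered for Beat and
# smoothly time-warped (monotone, bounded rate variation) for Improvise.
sim_strike_times <- function(n, trial_s, playing, jitter_sd = 0.02) {
  lo <- 2.5; hi <- trial_s - 2.5
  if (n == 1L) return((lo + hi) / 2)
  u <- seq(lo, hi, length.out = n)
  t <- if (identical(as.character(playing), "Improvise")) {
    phase <- runif(1, 0, 2 * pi)
    u + 1.2 * sin(2 * pi * 2.5 * (u - lo) / (hi - lo) + phase) +
      rnorm(n, 0, jitter_sd)
  } else {
    u + rnorm(n, 0, jitter_sd)
  }
  sort(pmin(trial_s - 1.2, pmax(1.2, t)))
}

# Add a template pulse into signal `v` at each time in `at` (seconds).
add_pulses <- function(v, fs, at, template) {
  half <- (length(template) - 1L) %/% 2L
  n <- length(v)
  for (tc in at) {
    c0 <- round(tc * fs) + 1L
    i0 <- max(1L, c0 - half); i1 <- min(n, c0 + half)
    if (i0 > i1) next
    j0 <- i0 - (c0 - half) + 1L
    v[i0:i1] <- v[i0:i1] + template[j0:(j0 + (i1 - i0))]
  }
  v
}

raised_cosine <- function(width_s, fs, amp = 1) {
  half <- round(width_s * fs / 2)
  t <- (-half:half) / fs
  amp * 0.5 * (1 + cos(pi * t / (width_s / 2)))
}

# IBI sequence hitting the programmed mean and RMSSD exactly (deviations are
# recentered and rescaled), so closed-loop tolerances test the detector.
sim_ibis <- function(n_ibi, ibi_mean_s, rmssd_s) {
  if (n_ibi < 2L) return(rep(ibi_mean_s, n_ibi))
  w <- rnorm(n_ibi)
  w <- w - mean(w)
  r <- sqrt(mean(diff(w)^2))
  if (r > 0 && rmssd_s > 0) w <- w * (rmssd_s / r) else w <- w * 0
  ibis <- ibi_mean_s + w
  if (any(ibis <= 0.25))
    abort("sim_ibis: programmed RMSSD implies non-physiological intervals")
  ibis
}

sim_ecg_channel <- function(cfg, trial_s, hr, rmssd_ms, noise_mv = NULL,
                            drift_mv = 0) {
  fs <- cfg$fs
  ibi <- 60 / hr
  n_beat <- floor((trial_s - 1.4) / ibi) + 1L
  ibis <- sim_ibis(n_beat - 1L, ibi, rmssd_ms / 1000)
  r_times <- 0.5 + cumsum(c(0, ibis))
  # 80 ms raised-cosine support, exponentiated so the apex is sharp enough
  # for sample-accurate localization (a real R wave's steep upstroke)
  tpl <- cfg$ecg$amp_mv *
    (raised_cosine(0.08, fs) ^ (cfg$ecg$r_sharpness %||% 6))
  n <- round(trial_s * fs)
  noise <- noise_mv %||% cfg$ecg$noise_mv
  v <- rnorm(n, 0, noise)
  if (drift_mv != 0) v <- v + seq(0, drift_mv, length.out = n)
  v <- add_pulses(v, fs, r_times, tpl)
  channel_signal(v, fs, "ecg", "mV")
}

sim_eda_channel <- function(cfg, trial_s, level, clip = FALSE) {
  fs <- cfg$fs_eda
  n <- round(trial_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- runif(1, 0, 2 * pi)
  v <- level + cfg$eda$drift_us * sin(2 * pi * t / trial_s + phase) +
    rnorm(n, 0, cfg$eda$noise_us)
  if (clip) v <- pmin(v, quantile(v, 0.85))
  channel_signal(pmax(v, 0), fs, "eda", "uS")
}

sim_emg_channel <- function(cfg, trial_s, strike_times, amp_frac, mvc_mv,
                            modality) {
  fs <- cfg$fs
  n <- round(trial_s * fs)
  v <- rnorm(n, 0, cfg$emg$noise_mv)
  width <- cfg$emg$burst_ms / 1000
  half <- round(width * fs / 2)
  tt <- (-half:half) / fs
  hann <- 0.5 * (1 + cos(pi * tt / (width / 2)))
  for (tc in strike_times) {
    phase <- runif(1, 0, 2 * pi)
    burst <- amp_frac * mvc_mv * sqrt(2) * hann *
      sin(2 * pi * cfg$emg$carrier_hz * (tt + tc) + phase)
    c0 <- round(tc * fs) + 1L
    i0 <- max(1L, c0 - half); i1 <- min(n, c0 + half)
    j0 <- i0 - (c0 - half) + 1L
    v[i0:i1] <- v[i0:i1] + burst[j0:(j0 + (i1 - i0))]
  }
  channel_signal(v, fs, modality, "mV")
}

sim_accel_channels <- function(cfg, trial_s, strike_times, amp_g, legacy_y) {
  fs <- cfg$fs
  n <- round(trial_s * fs)
  tpl_z <- raised_cosine(cfg$accel$pulse_ms / 1000, fs, amp_g)
  tpl_xy <- raised_cosine(cfg$accel$pulse_ms / 1000, fs,
                          cfg$accel$xy_frac * amp_g)
  z <- add_pulses(rnorm(n, 0, cfg$accel$noise_g) + 1, fs, strike_times, tpl_z)
  x <- add_pulses(rnorm(n, 0, cfg$accel$noise_g), fs, strike_times, tpl_xy)
  if (legacy_y) {
    fs_y <- 250
    ny <- round(trial_s * fs_y)
    tpl_y <- raised_cosine(cfg$accel$pulse_ms / 1000, fs_y,
                           cfg$accel$xy_frac * amp_g)
    y <- add_pulses(rnorm(ny, 0, cfg$accel$noise_g), fs_y, strike_times, tpl_y)
    y_sig <- channel_signal(y, fs_y, "accel_y", "g")
  } else {
    y <- add_pulses(rnorm(n, 0, cfg$accel$noise_g), fs, strike_times, tpl_xy)
    y_sig <- channel_signal(y, fs, "accel_y", "g")
  }
  list(x = channel_signal(x, fs, "accel_x", "g"),
       y = y_sig,
       z = channel_signal(z, fs, "accel_z", "g"))
}

#' Synthesize the raw signals of one trial
#'
#' Generates all modalities for a playing trial (EMG flexor/extensor bursts
#' and accelerometer transients at the planted strike times, a QRS-template
#' ECG train at the programmed heart rate and RMSSD, tonic EDA with slow
#' drift, and MIDI note-on events) or the EDA/ECG pair of a listen-only
#' trial. Reproducible via the trial's derived seed.
#'
#' @param study A `drum_study`.
#' @param trial_id Trial identifier from the study manifest.
#' @return List with `meta` (manifest row), `channels` (named list of
#'   [channel_signal()]), `midi` (note-event tibble or NULL) and
#'   `strike_times` (generator truth; NULL for listen-only).
#' @export
simulate_trial_signals <- function(study, trial_id) {
  stopifnot(inherits(study, "drum_study"))
  cfg <- study$config
  meta <- study$manifest[study$manifest$trial_id == trial_id, ]
  if (nrow(meta) != 1L) abort(sprintf("unknown trial_id '%s'", trial_id))
  if (meta$is_listen_only) {
    row <- study$listen[study$listen$trial_id == trial_id, ]
    return(with_seed(row$trial_seed, {
      list(meta = meta,
           channels = list(
             eda = sim_eda_channel(cfg, cfg$trial_s, row$eda_level),
             ecg = sim_ecg_channel(cfg, cfg$trial_s, row$hr_rest,
                                   row$rmssd_rest)),
           midi = NULL, strike_times = NULL)
    }))
  }
  row <- study$trials[study$trials$trial_id == trial_id, ]
  subj_idx <- match(row$subject_id, study$participants$subject_id)
  legacy_y <- subj_idx <= cfg$n_legacy_y_subjects
  mvc <- study$mvc[study$mvc$subject_id == row$subject_id, ]
  with_seed(row$trial_seed, {
    st <- sim_strike_times(row$strike_count, cfg$trial_s,
                           row$playing_condition)
    ecg_noise <- if (trial_id %in% cfg$qc_scenarios$ecg_low_snr)
      cfg$ecg$amp_mv else cfg$ecg$noise_mv
    channels <- c(
      list(
        emg_flexor = sim_emg_channel(cfg, cfg$trial_s, st,
                                     row$mean_emg_pct_mvc, mvc$flexor,
                                     "emg_flexor"),
        emg_extensor = sim_emg_channel(cfg, cfg$trial_s, st,
                                       row$mean_emg_pct_mvc, mvc$extensor,
                                       "emg_extensor")),
      sim_accel_channels(cfg, cfg$trial_s, st, row$accel_amp_g, legacy_y) |>
        setNames(c("accel_x", "accel_y", "accel_z")),
      list(
        ecg = sim_ecg_channel(cfg, cfg$trial_s, row$bpm, row$rmssd,
                              noise_mv = ecg_noise),
        eda = sim_eda_channel(cfg, cfg$trial_s, row$eda_trial_level,
                              clip = trial_id %in% cfg$qc_scenarios$eda_ceiling))
    )
    midi <- tibble(onset_s = st, note = 38L,
                   velocity = as.integer(sample(40:120, length(st),
                                                replace = TRUE)),
                   channel = 9L)
    list(meta = meta, channels = channels, midi = midi, strike_times = st)
  })
}

#' Synthesize a subject's MVC calibration trace
#'
#' A 5-second rectified-style recording per muscle: low background activity
#' with a 1.4-second maximal-effort plateau whose carrier amplitude encodes
#' the subject's MVC, so that band-pass filtering, RMS rectification and the
#' maximum one-second-window rule recover the MVC constant.
#'
#' @param study A `drum_study`.
#' @param subject_id Subject identifier.
#' @return Named list (`flexor`, `extensor`) of [channel_signal()] objects.
#' @export
simulate_mvc_trace <- function(study, subject_id) {
  cfg <- study$config
  mvc <- study$mvc[study$mvc$subject_id == subject_id, ]
  if (nrow(mvc) != 1L) abort(sprintf("unknown subject '%s'", subject_id))
  with_seed(mvc$seed, {
    fs <- cfg$fs; dur <- 5
    n <- dur * fs
    t <- (seq_len(n) - 1) / fs
    mk <- function(level, modality) {
      envl <- 0.15 * level +
        (level - 0.15 * level) * (t >= 1.8 & t < 3.2)   # plateau 1.4 s
      v <- envl * sqrt(2) * sin(2 * pi * cfg$emg$carrier_hz * t +
                                  runif(1, 0, 2 * pi)) +
        rnorm(n, 0, cfg$emg$noise_mv)
      channel_signal(v, fs, modality, "mV")
    }
    list(flexor = mk(mvc$flexor, "emg_flexor"),
         extensor = mk(mvc$extensor, "emg_extensor"))
  })
}
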