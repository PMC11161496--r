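# End-to-end orchestration: derive the per-trial measures table from a study
# (synthesized in memory or read from disk), fit the per-outcome mixed models
# and assemble the chi-square/p report grid.

OUTCOME_LABELS <- c(
  pc_reward = "Reward", pc_challenge = "Challenge",
  total_acceleration = "Total Acceleration", mean_emg_pct_mvc = "Mean EMG",
  strike_count = "Drum Strike Count", tonic_eda_delta = "Tonic EDA",
  bpm = "BPM", rmssd = "HRV")

AUTONOMIC_OUTCOMES <- c("tonic_eda_delta", "bpm", "rmssd")

get_trial_recording <- function(study, trial_id) {
  if (is.null(study$dir)) simulate_trial_signals(study, trial_id)
  else read_trial_recording(study$dir, study, trial_id)
}

get_mvc_traces <- function(study, subject_id) {
  if (is.null(study$dir)) simulate_mvc_trace(study, subject_id)
  else {
    p <- file.path(study$dir, paste0("mvc_", subject_id, ".csv"))
    ch <- read_signal_table(p, paste0(p, ".schema.json"))
    list(flexor = ch$emg_flexor, extensor = ch$emg_extensor)
  }
}

#' Derive the measures of a single trial recording
#'
#' Runs every signal stage on one playing trial: accelerometry preprocessing,
#' magnitude and total acceleration; per-muscle EMG band-pass, RMS envelope,
#' MVC normalization, accelerometer-aligned movement peaks, 10% low-peak trim
#' and the flexor/extensor-averaged mean peak activation; MIDI strike count;
#' ECG quality check, R-wave detection, BPM and RMSSD; EDA quality check,
#' tonic level and listen-only baseline correction. Quality-flagged
#' modalities yield explicit missing values, never silent zeros.
#'
#' @param recording List with `channels` (named [channel_signal()] list) and
#'   `midi` (note-event tibble), as from [simulate_trial_signals()].
#' @param mvc Named numeric vector `c(flexor=, extensor=)` of MVC constants
#'   in envelope units.
#' @param listen_tonic The subject's listen-only tonic EDA level (or `NA`).
#' @param trial_s Trial duration in seconds.
#' @param params Processing parameters (drop fraction, alignment tolerance,
#'   peak-detection settings); see [pipeline_params()].
#' @return One-row tibble of measures plus a `qc_flags` character column
#'   (flags joined by `;`).
#' @export
derive_trial_measures <- function(recording, mvc, listen_tonic = NA,
                                  trial_s = 60, params = pipeline_params()) {
  ch <- recording$channels
  flags <- character(0)

  proc <- preprocess_accel(ch$accel_x, ch$accel_y, ch$accel_z,
                           target_fs = params$accel_target_fs,
                           highpass_hz = params$accel_highpass_hz,
                           trim_s = params$accel_trim_s)
  total_acc <- total_acceleration(accel_magnitude(proc$x, proc$y, proc$z))
  apk <- detect_accel_peaks(proc, k_mad = params$accel_peak_k_mad,
                            min_sep_ms = params$accel_peak_min_sep_ms)
  if (length(apk) == 0L) flags <- c(flags, "no_accel_peaks")

  muscle_mean <- function(sig, mvc_val) {
    env <- rms_envelope(bandpass_emg(sig), fs = sig$fs,
                        window_ms = params$emg_rms_window_ms)
    env <- normalize_emg(env, mvc_val)
    pk <- detect_movement_peaks(env, apk, tol_ms = params$align_tolerance_ms,
                                noise_floor = params$emg_noise_floor)
    pk <- trim_low_peaks(pk, params$emg_drop_fraction)
    list(mean = mean_peak_activation(pk),
         n_unmatched = attr(pk, "n_unmatched") %||% 0L,
         n_retained = nrow(pk))
  }
  fl <- muscle_mean(ch$emg_flexor, mvc[["flexor"]])
  ex <- muscle_mean(ch$emg_extensor, mvc[["extensor"]])
  mean_emg <- mean(c(fl$mean, ex$mean))
  if (is.na(mean_emg)) flags <- c(flags, "emg_no_peaks")

  strike_count <- if (is.null(recording$midi)) NA_integer_
    else drum_strike_count(recording$midi, 0, trial_s)

  ecg_flags <- autonomic_qc(ch$ecg, "ecg", snr_min = params$ecg_snr_min)
  flags <- c(flags, ecg_flags)
  if (length(ecg_flags) == 0L) {
    r <- tryCatch(detect_r_waves(ch$ecg,
                                 dedup_threshold = params$ecg_dedup_threshold,
                                 window_s = params$ecg_window_s,
                                 min_sep_ms = params$ecg_min_sep_ms),
                  error = function(e) NULL)
    if (is.null(r) || length(r$r_indices) < 3L) {
      flags <- c(flags, "ecg_detection_failed")
      bpm_v <- NA_real_; rmssd_v <- NA_real_
    } else {
      bpm_v <- bpm(r); rmssd_v <- rmssd(r)
    }
  } else { bpm_v <- NA_real_; rmssd_v <- NA_real_ }

  eda_flags <- autonomic_qc(ch$eda, "eda")
  flags <- c(flags, eda_flags)
  if (length(eda_flags) == 0L) {
    delta <- baseline_correct_eda(tonic_eda(ch$eda), listen_tonic)
    if (!is.null(attr(delta, "qc"))) flags <- c(flags, attr(delta, "qc"))
    eda_delta <- as.numeric(delta)
  } else eda_delta <- NA_real_

  tibble(
    mean_emg_pct_mvc = mean_emg,
    total_acceleration = total_acc,
    strike_count = strike_count,
    tonic_eda_delta = eda_delta,
    bpm = bpm_v,
    rmssd = rmssd_v,
    n_movement_peaks = fl$n_retained,
    n_unmatched_peaks = fl$n_unmatched + ex$n_unmatched,
    qc_flags = paste(unique(flags), collapse = ";")
  )
}

#' Processing parameters of the derivation pipeline
#'
#' All signal-processing tunables in one place, with the defaults used
#' throughout: 10-400 Hz EMG band, 10 ms RMS windows, 10% low-peak drop,
#' 250 Hz accelerometry target with 0.5 Hz gravity high-pass, 100 ms
#' EMG-accelerometer alignment tolerance, and the ECG 80%/1-s deduplication
#' rule with 250 ms minimum separation.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    emg_rms_window_ms = 10, emg_drop_fraction = 0.10, emg_noise_floor = 0,
    accel_target_fs = 250, accel_highpass_hz = 0.5, accel_trim_s = 1,
    accel_peak_k_mad = 8, accel_peak_min_sep_ms = 150,
    align_tolerance_ms = 100,
    ecg_dedup_threshold = 0.8, ecg_window_s = 1.0, ecg_min_sep_ms = 250,
    ecg_snr_min = 8)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  utils::modifyList(p, over)
}

#' Derive the full per-trial measures table of a study
#'
#' Computes each subject's MVC constants from the MVC calibration traces and
#' the listen-only tonic EDA baseline, derives every playing trial's measures
#' with [derive_trial_measures()], merges the survey responses, and reduces
#' the 12 items by parallel analysis + PCA into oriented reward/challenge
#' scores. QC exclusions are applied per outcome; the component model, the
#' parallel analysis and a QC log are attached as attributes.
#'
#' @param study A `drum_study` (in-memory, or disk-backed via [read_study()]).
#' @param params [pipeline_params()].
#' @param pa_seed Seed for the parallel-analysis reference simulation.
#' @param progress Print progress every 50 trials.
#' @return Tibble with one row per playing trial: design columns, participant
#'   covariates, derived measures, survey items and `pc_reward` /
#'   `pc_challenge` scores. Attributes: `component_model`,
#'   `parallel_analysis`, `qc_log`.
#' @export
derive_measures <- function(study, params = pipeline_params(),
                            pa_seed = study$seed + 1L, progress = FALSE) {
  stopifnot(inherits(study, "drum_study"))
  trial_s <- study$config$trial_s

  mvc_tab <- map_dfr(study$participants$subject_id, function(sid) {
    tr <- get_mvc_traces(study, sid)
    one <- function(sig) compute_mvc(rms_envelope(bandpass_emg(sig), fs = sig$fs,
                                                  window_ms = params$emg_rms_window_ms))
    tibble(subject_id = sid, flexor = one(tr$flexor),
           extensor = one(tr$extensor))
  })

  listen_tab <- map_dfr(seq_len(nrow(study$listen)), function(i) {
    id <- study$listen$trial_id[i]
    rec <- get_trial_recording(study, id)
    fl <- autonomic_qc(rec$channels$eda, "eda")
    tibble(subject_id = study$listen$subject_id[i],
           listen_tonic = if (length(fl)) NA_real_
                          else tonic_eda(rec$channels$eda),
           listen_flags = paste(fl, collapse = ";"))
  })

  play <- study$manifest[!study$manifest$is_listen_only, ]
  rows <- vector("list", nrow(play))
  for (i in seq_len(nrow(play))) {
    id <- play$trial_id[i]
    sid <- play$subject_id[i]
    rec <- get_trial_recording(study, id)
    mvc <- mvc_tab[mvc_tab$subject_id == sid, ]
    lt <- listen_tab$listen_tonic[listen_tab$subject_id == sid]
    if (length(lt) == 0L) lt <- NA_real_
    rows[[i]] <- bind_cols(
      play[i, c("trial_id", "subject_id", "playing_condition",
                "accompaniment", "style", "order_position")],
      derive_trial_measures(rec, c(flexor = mvc$flexor,
                                   extensor = mvc$extensor),
                            listen_tonic = lt, trial_s = trial_s,
                            params = params))
    if (progress && i %% 50 == 0)
      message(sprintf("derived %d/%d trials", i, nrow(play)))
  }
  measures <- bind_rows(rows) |>
    left_join(study$participants, by = "subject_id") |>
    left_join(study$surveys, by = c("trial_id", "subject_id"))

  items <- as.matrix(measures[, survey_items])
  pa <- parallel_analysis(items, seed = pa_seed)
  k_fit <- max(2L, pa$n_components)
  cm <- orient_and_label(fit_pca(items, k_fit))
  measures$pc_reward <- cm$scores[, 1]
  measures$pc_challenge <- cm$scores[, 2]
  measures$synchrony_rating <- measures$synchrony

  qc_log <- measures |>
    filter(.data$qc_flags != "") |>
    select("trial_id", "subject_id", "qc_flags")

  attr(measures, "component_model") <- cm
  attr(measures, "parallel_analysis") <- pa
  attr(measures, "qc_log") <- qc_log
  measures
}

#' Fit the condition model for every outcome
#'
#' @param measures Measures tibble from [derive_measures()] (or
#'   [simulate_measures()]).
#' @param outcomes Outcome columns to model.
#' @inheritParams fit_condition_model
#' @return Named list of `drum_lmm` objects.
#' @export
fit_all_condition_models <- function(measures, outcomes = names(OUTCOME_LABELS),
                                     df_method = "satterthwaite") {
  setNames(lapply(outcomes, function(oc)
    fit_condition_model(measures, oc, df_method = df_method)), outcomes)
}

#' Assemble the chi-square / p report grid
#'
#' One row per outcome, one column pair per predictor (playing condition,
#' accompaniment, their interaction, composition style, BMRQ, Gold-MSI, and
#' the total-acceleration covariate, which is NA for non-autonomic outcomes).
#' Optionally written as machine-readable JSON alongside the printable grid.
#'
#' @param models Named list of `drum_lmm` objects from
#'   [fit_all_condition_models()].
#' @param path Optional JSON output path.
#' @return A list with `grid` (wide display tibble with `chisq (p)` cells)
#'   and `long` (tidy term-by-outcome tibble), invisibly written to `path`
#'   when given.
#' @export
run_report <- function(models, path = NULL) {
  term_order <- c("playing", "accompaniment", "interaction", "style",
                  "bmrq", "gold_msi", "total_acceleration")
  long <- map_dfr(names(models), function(oc) {
    w <- models[[oc]]$wald |> mutate(outcome = OUTCOME_LABELS[[oc]] %||% oc)
    missing_terms <- setdiff(term_order, w$term)
    bind_rows(w, tibble(term = missing_terms, chisq = NA_real_,
                        df = NA_real_, p = NA_real_,
                        outcome = OUTCOME_LABELS[[oc]] %||% oc))
  }) |>
    mutate(term = factor(.data$term, term_order)) |>
    filter(!is.na(.data$term)) |>
    arrange(.data$outcome, .data$term)
  grid <- long |>
    mutate(cell = ifelse(is.na(.data$chisq), "NA",
                         sprintf("%.2f (%s)", .data$chisq,
                                 ifelse(.data$p < 0.001, "< 0.001",
                                        sprintf("%.3f", .data$p))))) |>
    select("outcome", "term", "cell") |>
    tidyr::pivot_wider(names_from = "term", values_from = "cell")
  grid <- grid[match(unname(OUTCOME_LABELS[names(models)]), grid$outcome), ]
  if (!is.null(path))
    jsonlite::write_json(list(grid = grid, terms = long), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  list(grid = grid, long = long)
}

# ---- study (de)serialization -----------------------------------------------

#' Write a synthetic study to disk
#'
#' Materializes the dataset in the exact formats the readers consume:
#' `manifest.csv`, `participants.csv`, `surveys.csv`, per-trial signal CSVs
#' with JSON sidecar schemas (one file per sampling rate), Standard MIDI
#' files, and per-subject MVC calibration traces.
#'
#' @param study A `drum_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "drum_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  readr::write_csv(study$participants[, c("subject_id", "bmrq_total",
                                          "gold_msi_training")],
                   file.path(dir, "participants.csv"), progress = FALSE)
  readr::write_csv(study$surveys, file.path(dir, "surveys.csv"),
                   progress = FALSE)
  for (sid in study$participants$subject_id) {
    tr <- simulate_mvc_trace(study, sid)
    write_signal_table(list(emg_flexor = tr$flexor, emg_extensor = tr$extensor),
                       file.path(dir, paste0("mvc_", sid, ".csv")))
  }
  for (id in study$manifest$trial_id) {
    rec <- simulate_trial_signals(study, id)
    fast <- rec$channels[map_dbl(rec$channels, "fs") == study$config$fs]
    slow <- rec$channels[map_dbl(rec$channels, "fs") != study$config$fs]
    if (length(fast))
      write_signal_table(fast, file.path(dir, paste0(id, "_fast.csv")))
    if (length(slow)) {
      sfs <- unique(map_dbl(slow, "fs"))
      for (f in sfs)
        write_signal_table(slow[map_dbl(slow, "fs") == f],
                           file.path(dir, sprintf("%s_slow%d.csv", id, round(f))))
    }
    if (!is.null(rec$midi))
      write_midi(rec$midi, file.path(dir, paste0(id, ".mid")))
  }
  jsonlite::write_json(list(seed = study$seed, trial_s = study$config$trial_s,
                            fs = study$config$fs),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

read_trial_recording <- function(dir, study, trial_id) {
  channels <- list()
  for (p in Sys.glob(file.path(dir, paste0(trial_id, "_*.csv")))) {
    if (grepl("schema", p)) next
    channels <- c(channels, read_signal_table(p, paste0(p, ".schema.json")))
  }
  midi_path <- file.path(dir, paste0(trial_id, ".mid"))
  midi <- if (file.exists(midi_path)) read_midi_events(midi_path) else NULL
  meta <- study$manifest[study$manifest$trial_id == trial_id, ]
  list(meta = meta, channels = channels, midi = midi, strike_times = NULL)
}

#' Read a study back from disk
#'
#' Counterpart of [write_study()]: loads the manifest, participant and survey
#' tables and returns a disk-backed `drum_study` whose recordings are read
#' lazily by [derive_measures()].
#'
#' @param dir Study directory.
#' @return A `drum_study` with `dir` set.
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"))
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  participants <- read_participants(file.path(dir, "participants.csv"))
  surveys <- read_survey(file.path(dir, "surveys.csv"))
  structure(
    list(config = sim_config(n_subjects = nrow(participants),
                             trial_s = meta$trial_s, fs = meta$fs),
         seed = meta$seed, participants = participants,
         manifest = manifest,
         trials = manifest[!manifest$is_listen_only, ],
         listen = manifest[manifest$is_listen_only, ],
         surveys = surveys, mvc = NULL, dir = dir),
    class = "drum_study")
}
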