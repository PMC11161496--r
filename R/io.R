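#' Read a columnar time-series file into channel signals
#'
#' Reads a CSV/TSV file whose first column is time (seconds) or sample index
#' and whose remaining columns are channel traces, using a sidecar schema that
#' declares the sampling rate and per-channel units. Input is validated, not
#' coerced: non-numeric values, missing declared channels and non-uniform
#' sampling are errors naming the offending record.
#'
#' @param path Path to a CSV (or TSV) file with a `time` or `sample` column.
#' @param schema Either a list with elements `fs` (samples/second) and
#'   `channels` (named list mapping column name to a list with `modality` and
#'   `units`), or a path to a JSON file holding that structure.
#' @param tol Tolerance on time-step uniformity, as a multiple of `1/fs`
#'   (default 0.5: a gap larger than 1.5 samples is rejected).
#' @return Named list of [channel_signal()] objects, one per declared channel.
#' @export
read_signal_table <- function(path, schema, tol = 0.5) {
  schema <- load_schema(schema)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(tab) == 0L) abort(sprintf("%s: no samples", path))
  fs <- schema$fs
  time_col <- intersect(c("time", "sample"), names(tab))[1]
  if (!is.na(time_col)) {
    tvals <- tab[[time_col]]
    if (!is.numeric(tvals)) abort(sprintf("%s: non-numeric %s column", path, time_col))
    if (length(tvals) > 1L) {
      step <- if (time_col == "time") 1 / fs else 1
      dt <- diff(tvals)
      bad <- which(abs(dt - step) > tol * step)
      if (length(bad) > 0L)
        abort(sprintf("%s: non-uniform sampling at row %d (step %.6g, expected %.6g)",
                      path, bad[1] + 1L, dt[bad[1]], step))
    }
  }
  out <- list()
  for (ch in names(schema$channels)) {
    if (!ch %in% names(tab))
      abort(sprintf("%s: missing column '%s' declared in schema", path, ch))
    v <- tab[[ch]]
    if (!is.numeric(v))
      abort(sprintf("%s: non-numeric values in column '%s'", path, ch))
    if (anyNA(v))
      abort(sprintf("%s: missing value in column '%s' at row %d",
                    path, ch, which(is.na(v))[1]))
    spec <- schema$channels[[ch]]
    out[[ch]] <- channel_signal(v, fs = spec$fs %||% fs,
                                modality = spec$modality,
                                units = spec$units %||% NA_character_)
  }
  out
}

load_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- jsonlite::read_json(schema, simplifyVector = FALSE)
  if (is.null(schema$fs) || is.null(schema$channels))
    abort("schema must declare fs and channels")
  schema$fs <- as.numeric(schema$fs)
  schema
}

#' Write channel signals to a columnar CSV with a JSON sidecar schema
#'
#' Channels sharing the file's base sampling rate go into one table with a
#' `time` column; a channel at a different rate must be written separately.
#'
#' @param channels Named list of [channel_signal()] objects with equal `fs`
#'   and length.
#' @param path Output CSV path; the schema is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(channels, path) {
  fs <- unique(map_dbl(channels, "fs"))
  if (length(fs) != 1L) abort("write_signal_table: channels must share one fs")
  ns <- unique(map_int(channels, ~ length(.x$samples)))
  if (length(ns) != 1L) abort("write_signal_table: channels must share one length")
  tab <- tibble(time = (seq_len(ns) - 1) / fs)
  for (ch in names(channels)) tab[[ch]] <- channels[[ch]]$samples
  readr::write_csv(tab, path, progress = FALSE)
  schema <- list(
    fs = fs,
    channels = lapply(channels, function(c)
      list(modality = c$modality, units = c$units))
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial manifest
#'
#' The manifest lists every trial of the study: subject, playing condition
#' (Improvise/Beat), accompaniment (Live/Recorded), composition style, order
#' position 1-16, and a listen-only flag for the EDA baseline trial. Unknown
#' labels and duplicated condition cells are rejected.
#'
#' @param path CSV with columns `subject_id`, `playing_condition`,
#'   `accompaniment`, `style`, `order_position`, `is_listen_only`.
#' @return A tibble of trial metadata with condition columns as factors.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("subject_id", "playing_condition", "accompaniment", "style",
            "order_position", "is_listen_only")
  miss <- setdiff(need, names(m))
  if (length(miss)) abort(paste0("manifest: missing column(s) ",
                                 paste(miss, collapse = ", ")))
  m$is_listen_only <- as.logical(m$is_listen_only)
  play <- m[!m$is_listen_only, ]
  check_labels <- function(x, allowed, what) {
    bad <- setdiff(unique(as.character(x)), allowed)
    if (length(bad))
      abort(sprintf("manifest: unknown %s '%s' (allowed: %s)",
                    what, bad[1], paste(allowed, collapse = ", ")))
  }
  check_labels(play$playing_condition, PLAYING_LEVELS, "playing_condition")
  check_labels(play$accompaniment, ACCOMP_LEVELS, "accompaniment")
  check_labels(play$style, STYLE_LEVELS, "style")
  dup <- play |>
    dplyr::count(.data$subject_id, .data$playing_condition,
                 .data$accompaniment, .data$style) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L)
    abort(sprintf(
      "manifest: duplicate trial for subject %s (%s, %s, %s)",
      dup$subject_id[1], dup$playing_condition[1], dup$accompaniment[1],
      dup$style[1]))
  m |>
    mutate(
      subject_id = as.character(.data$subject_id),
      playing_condition = factor(.data$playing_condition, PLAYING_LEVELS),
      accompaniment = factor(.data$accompaniment, ACCOMP_LEVELS),
      style = factor(.data$style, STYLE_LEVELS),
      order_position = as.integer(.data$order_position)
    ) |>
    as_tibble()
}

#' Write / read the per-trial measures table
#'
#' Round-trip stable: writing then reading reproduces values to full double
#' precision (readr serializes doubles losslessly).
#'
#' @param measures A tibble of per-trial measures (one row per playing trial).
#' @param path Output CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_measures <- function(measures, path) {
  # doubles serialized at 17 significant digits: bit-exact round trip
  out <- measures |>
    mutate(across(dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  # base parser (strtod): correctly rounded, so 17-digit output is bit-exact
  m <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (col in intersect(c("playing_condition", "accompaniment", "style"), names(m))) {
    lev <- switch(col, playing_condition = PLAYING_LEVELS,
                  accompaniment = ACCOMP_LEVELS, style = STYLE_LEVELS)
    m[[col]] <- factor(m[[col]], lev)
  }
  if ("subject_id" %in% names(m)) m$subject_id <- as.character(m$subject_id)
  m
}

#' Read the per-trial survey table
#'
#' @param path CSV with trial identifiers (`subject_id`, `trial_id`) and the
#'   12 item columns named per [survey_items].
#' @return A tibble; Likert values outside 1-5 are rejected.
#' @export
read_survey <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(survey_items, names(s))
  if (length(miss)) abort(paste0("survey: missing item column(s) ",
                                 paste(miss, collapse = ", ")))
  for (it in survey_items) {
    v <- s[[it]]
    bad <- which(!v %in% 1:5)
    if (length(bad))
      abort(sprintf("survey: item '%s' out of 1-5 range at row %d", it, bad[1]))
  }
  s
}

#' Read the participant table
#'
#' Applies the inclusion screen on musical-reward sensitivity: participants
#' with a Barcelona Music Reward Questionnaire total below 65 are flagged.
#'
#' @param path CSV with columns `subject_id`, `bmrq_total`, `gold_msi_training`.
#' @return A tibble with an added logical `included` column (`bmrq_total >= 65`).
#' @export
read_participants <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "bmrq_total", "gold_msi_training")
  miss <- setdiff(need, names(p))
  if (length(miss)) abort(paste0("participants: missing column(s) ",
                                 paste(miss, collapse = ", ")))
  p |> mutate(subject_id = as.character(.data$subject_id),
              included = .data$bmrq_total >= 65)
}
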