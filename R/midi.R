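# Minimal Standard MIDI File support: enough to write drum-pad performances
# (note events on one channel, optional tempo changes) and to read back note
# onsets in absolute seconds through the file's tempo map. Formats 0 and 1,
# ticks-per-quarter division only (SMPTE division is rejected).

vlq_encode <- function(value) {
  stopifnot(value >= 0)
  bytes <- value %% 128L
  value <- value %/% 128L
  while (value > 0L) {
    bytes <- c(value %% 128L + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

u16 <- function(x) as.raw(c(x %/% 256L, x %% 256L))
u32 <- function(x) as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
                            (x %/% 256L) %% 256L, x %% 256L))

#' Write note events to a Standard MIDI File
#'
#' Writes a single-track (format 0) file holding the given note onsets at a
#' fixed tempo. Each note gets a note-on at its onset and a note-off (note-on
#' with velocity 0, the running-status dialect) after `dur_s`.
#'
#' @param notes Tibble/data frame with columns `onset_s` and optionally
#'   `note` (default 38), `velocity` (default 80), `channel` (default 9).
#' @param path Output `.mid` path.
#' @param ppq Ticks per quarter note.
#' @param tempo_bpm Tempo in quarter notes per minute.
#' @param dur_s Note duration in seconds.
#' @return `path`, invisibly.
#' @export
write_midi <- function(notes, path, ppq = 480L, tempo_bpm = 120, dur_s = 0.05) {
  notes <- as_tibble(notes)
  if (is.null(notes$note)) notes$note <- 38L
  if (is.null(notes$velocity)) notes$velocity <- 80L
  if (is.null(notes$channel)) notes$channel <- 9L
  sec_per_tick <- 60 / (tempo_bpm * ppq)
  ev <- bind_rows(
    tibble(tick = round(notes$onset_s / sec_per_tick), on = TRUE,
           note = notes$note, vel = notes$velocity, chan = notes$channel),
    tibble(tick = round((notes$onset_s + dur_s) / sec_per_tick), on = FALSE,
           note = notes$note, vel = 0L, chan = notes$channel)
  ) |> arrange(.data$tick, dplyr::desc(.data$on))
  track <- c(
    as.raw(c(0x00, 0xFF, 0x51, 0x03)),                # tempo meta at tick 0
    as.raw(rev(as.integer(round(6e7 / tempo_bpm)) %/% 256L^(0:2) %% 256L))
  )
  last_tick <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last_tick
    last_tick <- ev$tick[i]
    status <- as.raw(0x90 + ev$chan[i])               # note-on; vel 0 = off
    track <- c(track, vlq_encode(delta), status,
               as.raw(ev$note[i]), as.raw(ev$vel[i]))
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("MThd"), u32(6L), u16(0L), u16(1L), u16(as.integer(ppq)),
             charToRaw("MTrk"), u32(length(track)), track), con)
  invisible(path)
}

#' Read note events from a Standard MIDI File
#'
#' Parses format 0 or 1 files and returns note-on events with velocity > 0
#' (velocity-0 note-ons are the conventional note-off dialect and are
#' excluded). Onsets are converted from ticks to absolute seconds through the
#' file's tempo map; the default tempo of 120 quarter notes per minute applies
#' before the first tempo event.
#'
#' @param path Path to a `.mid` file.
#' @return A tibble with columns `onset_s`, `note`, `velocity`, `channel`,
#'   ordered by onset. A file with no note events yields zero rows.
#' @export
read_midi_events <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  take <- function(n) {
    if (pos + n - 1L > length(bytes)) abort(sprintf("%s: truncated MIDI file", path))
    out <- bytes[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  rd_u32 <- function() sum(as.integer(take(4L)) * 256L^(3:0))
  rd_u16 <- function() sum(as.integer(take(2L)) * c(256L, 1L))
  rd_vlq <- function() {
    val <- 0
    repeat {
      b <- as.integer(take(1L))
      val <- val * 128 + (b %% 128L)
      if (b < 128L) return(val)
    }
  }
  if (rawToChar(take(4L)) != "MThd") abort(sprintf("%s: not a MIDI file", path))
  if (rd_u32() != 6L) abort(sprintf("%s: bad header length", path))
  format <- rd_u16(); ntrk <- rd_u16(); division <- rd_u16()
  if (!format %in% c(0L, 1L))
    abort(sprintf("%s: unsupported MIDI format %d", path, format))
  if (division >= 32768L)
    abort(sprintf("%s: SMPTE time division not supported", path))
  notes <- list(); tempos <- list()
  for (trk in seq_len(ntrk)) {
    if (rawToChar(take(4L)) != "MTrk") abort(sprintf("%s: missing MTrk", path))
    tlen <- rd_u32()
    tend <- pos + tlen
    tick <- 0; status <- NULL
    while (pos < tend) {
      tick <- tick + rd_vlq()
      b <- as.integer(take(1L))
      if (b >= 128L) { status <- b } else { pos <- pos - 1L }  # running status
      if (is.null(status)) abort(sprintf("%s: dangling data byte", path))
      hi <- status %/% 16L
      if (status == 255L) {                       # meta event
        type <- as.integer(take(1L)); mlen <- rd_vlq(); dat <- take(mlen)
        if (type == 0x51)
          tempos[[length(tempos) + 1L]] <-
            c(tick, sum(as.integer(dat) * 256L^(2:0)))
      } else if (status %in% c(240L, 247L)) {     # sysex
        take(rd_vlq())
      } else if (hi %in% c(8L, 9L)) {             # note off / note on
        note <- as.integer(take(1L)); vel <- as.integer(take(1L))
        if (hi == 9L && vel > 0L)
          notes[[length(notes) + 1L]] <-
            c(tick, note, vel, status %% 16L)
      } else if (hi %in% c(10L, 11L, 14L)) {      # two data bytes
        take(2L)
      } else if (hi %in% c(12L, 13L)) {           # one data byte
        take(1L)
      } else abort(sprintf("%s: unexpected status byte 0x%X", path, status))
    }
  }
  if (length(notes) == 0L)
    return(tibble(onset_s = numeric(), note = integer(),
                  velocity = integer(), channel = integer()))
  nm <- do.call(rbind, notes)
  onset_s <- ticks_to_seconds(nm[, 1], tempos, division)
  tibble(onset_s = onset_s, note = as.integer(nm[, 2]),
         velocity = as.integer(nm[, 3]), channel = as.integer(nm[, 4])) |>
    arrange(.data$onset_s)
}

# Convert absolute ticks to seconds under a tempo map
# (list of c(tick, us_per_quarter); default 500000 before the first entry).
ticks_to_seconds <- function(ticks, tempos, ppq) {
  if (length(tempos)) {
    tm <- do.call(rbind, tempos)
    tm <- tm[order(tm[, 1]), , drop = FALSE]
  } else tm <- matrix(numeric(0), ncol = 2)
  if (nrow(tm) == 0L || tm[1, 1] > 0) tm <- rbind(c(0, 500000), tm)
  # seconds elapsed at the start of each tempo segment
  seg_start <- tm[, 1]
  seg_us <- tm[, 2]
  sec_at <- cumsum(c(0, diff(seg_start) * head(seg_us, -1) / ppq / 1e6))
  idx <- findInterval(ticks, seg_start)
  sec_at[idx] + (ticks - seg_start[idx]) * seg_us[idx] / ppq / 1e6
}

#' Count drum strikes in a trial window
#'
#' Counts note-on events (velocity > 0) whose onset falls inside the half-open
#' window `[start, end)`, optionally restricted to one MIDI channel and/or
#' note number. Simultaneous note-ons each count once per event.
#'
#' @param events Tibble from [read_midi_events()].
#' @param start,end Window bounds in seconds (half-open).
#' @param channel,note Optional filters.
#' @return Integer count (0 for no events).
#' @export
drum_strike_count <- function(events, start = 0, end = Inf,
                              channel = NULL, note = NULL) {
  if (nrow(events) == 0L) return(0L)
  keep <- events$velocity > 0 & events$onset_s >= start & events$onset_s < end
  if (!is.null(channel)) keep <- keep & events$channel == channel
  if (!is.null(note)) keep <- keep & events$note == note
  sum(keep)
}
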