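test_that("note events survive a write/read cycle; velocity-0 is note-off", {
  notes <- tibble::tibble(onset_s = seq(0.5, 20, by = 0.47)[1:42],
                          note = 38L, velocity = 77L, channel = 9L)
  path <- withr::local_tempfile(fileext = ".mid")
  write_midi(notes, path)
  ev <- read_midi_events(path)
  # 42 note-ons come back; the paired velocity-0 note-offs are excluded
  expect_equal(nrow(ev), 42L)
  expect_true(all(ev$velocity > 0))
  expect_equal(ev$note, rep(38L, 42))
  # tick quantization at 960 ticks/s
  expect_equal(ev$onset_s, notes$onset_s, tolerance = 1 / 960)
})

test_that("onsets follow the tempo map across a mid-file tempo change", {
  # hand-built format-0 SMF, ppq = 480: tempo 120 bpm from tick 0,
  # 60 bpm from tick 960; notes at ticks 480, 960, 1440.
  # oracle by hand: tick 480 -> 0.5 s; tick 960 -> 1.0 s;
  # tick 1440 -> 1.0 + 480 ticks * (1e6 us / 480 ticks) = 2.0 s.
  track <- as.raw(c(
    0x00, 0xFF, 0x51, 0x03, 0x07, 0xA1, 0x20,       # tempo 500000
    0x83, 0x60, 0x99, 0x26, 0x50,                   # dt 480: note-on
    0x83, 0x60, 0xFF, 0x51, 0x03, 0x0F, 0x42, 0x40, # dt 480 (tick 960): tempo 1000000
    0x00, 0x99, 0x26, 0x50,                         # tick 960: note-on
    0x83, 0x60, 0x99, 0x26, 0x50,                   # dt 480 (tick 1440): note-on
    0x00, 0xFF, 0x2F, 0x00))
  hdr <- c(charToRaw("MThd"), as.raw(c(0, 0, 0, 6, 0, 0, 0, 1, 0x01, 0xE0)),
           charToRaw("MTrk"), as.raw(c(0, 0, 0, length(track))))
  path <- withr::local_tempfile(fileext = ".mid")
  writeBin(c(hdr, track), path)
  ev <- read_midi_events(path)
  expect_equal(ev$onset_s, c(0.5, 1.0, 2.0), tolerance = 1e-9)
  expect_equal(ev$channel, rep(9L, 3))
})

test_that("running status and empty files are handled", {
  # note-on, then a second note using running status (no status byte)
  track <- as.raw(c(0x00, 0x99, 0x26, 0x50,
                    0x60, 0x26, 0x00,          # running status, velocity 0 (off)
                    0x60, 0x26, 0x40,          # running status, real note-on
                    0x00, 0xFF, 0x2F, 0x00))
  hdr <- c(charToRaw("MThd"), as.raw(c(0, 0, 0, 6, 0, 0, 0, 1, 0x01, 0xE0)),
           charToRaw("MTrk"), as.raw(c(0, 0, 0, length(track))))
  path <- withr::local_tempfile(fileext = ".mid")
  writeBin(c(hdr, track), path)
  ev <- read_midi_events(path)
  expect_equal(nrow(ev), 2L)          # the velocity-0 event is excluded

  writeBin(charToRaw("nope"), path)
  expect_error(read_midi_events(path), "not a MIDI file")
})

test_that("drum_strike_count respects the half-open window and filters", {
  ev <- tibble::tibble(onset_s = c(seq(0.1, 41.1, by = 1), 60, 60.5, 61),
                       note = 38L, velocity = 80L, channel = 9L)
  expect_equal(drum_strike_count(ev, 0, 60), 42L)       # 3 events at/after end
  expect_equal(drum_strike_count(ev, 0, 30) +
                 drum_strike_count(ev, 30, 60), 42L)    # additive over windows
  expect_equal(drum_strike_count(ev[0, ], 0, 60), 0L)
  ev$channel[1] <- 3L
  expect_equal(drum_strike_count(ev, 0, 60, channel = 9), 41L)
  expect_equal(drum_strike_count(ev, 0, 60, note = 40), 0L)
})
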