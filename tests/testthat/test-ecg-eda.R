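test_that("BPM follows fs / mean(samples per beat) * 60", {
  expect_equal(bpm(seq(1, 120001, by = 2000), fs = 2000), 60)
  expect_equal(bpm(seq(1, 60001, by = 1000), fs = 2000), 120)
  expect_equal(bpm(cumsum(c(1, 1800, 2200)), fs = 2000), 60)  # mean spacing 2000
  expect_error(bpm(c(5L), fs = 2000), "at least 2")
  # identity: bpm * mean IBI in seconds = 60
  set.seed(2)
  idx <- cumsum(c(1, round(rnorm(30, 1500, 80))))
  expect_equal(bpm(idx, fs = 2000) * mean(diff(idx)) / 2000, 60)
})

test_that("RMSSD matches hand-worked interval examples", {
  fs <- 1000   # 1 sample = 1 ms
  expect_equal(rmssd(cumsum(c(1, rep(800, 10))), fs = fs), 0)
  expect_equal(rmssd(cumsum(c(1, 1000, 1010, 1000)), fs = fs),
               sqrt((10^2 + 10^2) / 2))
  expect_equal(rmssd(cumsum(c(1, 900, 1000, 1100, 1000)), fs = fs),
               sqrt((100^2 + 100^2 + 100^2) / 3))
  expect_error(rmssd(c(1L, 900L), fs = fs), "at least 3")
  # invariances: time translation; linear scaling of interval differences
  set.seed(5)
  idx <- cumsum(c(1, round(rnorm(40, 1000, 30))))
  expect_equal(rmssd(idx, fs = fs), rmssd(idx + 12345L, fs = fs))
  expect_equal(rmssd(cumsum(c(1, 1000 + 3 * (diff(idx) - 1000))), fs = fs),
               3 * rmssd(idx, fs = fs), tolerance = 1e-9)
})

test_that("R-wave detection hits planted beats and survives baseline drift", {
  fs <- 2000
  n <- 60 * fs
  tpl_half <- 80
  tpl <- (0.5 * (1 + cos(pi * (-tpl_half:tpl_half) / tpl_half)))^6
  at <- round(seq(0.5, 59.5, by = 1) * fs)      # 60 evenly spaced beats
  mk <- function(drift = 0) {
    v <- rnorm(n, 0, 0.001) + seq(0, drift, length.out = n)
    for (c0 in at) v[(c0 - tpl_half):(c0 + tpl_half)] <-
        v[(c0 - tpl_half):(c0 + tpl_half)] + tpl
    v
  }
  set.seed(8)
  r <- detect_r_waves(mk(), fs = fs)
  expect_equal(length(r$r_indices), 60L)
  expect_true(all(abs(r$r_indices - at) <= 1))

  set.seed(8)
  r2 <- detect_r_waves(mk(drift = 0.5), fs = fs)   # +0.5 mV linear drift
  expect_equal(r2$r_indices, r$r_indices)

  expect_error(detect_r_waves(rep(0, n), fs = fs), "insufficient R waves")
  expect_error(detect_r_waves(rnorm(2000), fs = 2000), "at least 5 s")
})

test_that("tonic EDA and baseline correction are means and differences", {
  expect_equal(tonic_eda(rep(4.2, 1000)), 4.2)
  expect_equal(tonic_eda(seq(2, 4, length.out = 5000)), 3)
  expect_equal(tonic_eda(rep(0, 100)), 0)

  expect_equal(baseline_correct_eda(5, 4), 1)
  expect_equal(baseline_correct_eda(4, 4), 0)
  missing <- baseline_correct_eda(5, NA)
  expect_true(is.na(missing))
  expect_equal(attr(missing, "qc"), "eda_no_baseline")
})

test_that("QC flags fire on ceiling-clipped EDA and low-SNR ECG", {
  set.seed(12)
  t <- seq(0, 60, by = 1 / 250)
  eda <- 5 + 0.3 * sin(2 * pi * t / 60) + rnorm(length(t), 0, 0.01)
  clipped <- pmin(eda, quantile(eda, 0.85))
  expect_true("eda_ceiling" %in% autonomic_qc(clipped, "eda"))
  expect_length(autonomic_qc(eda, "eda"), 0)
  expect_true("eda_flat" %in% autonomic_qc(rep(4, 1000), "eda"))

  st <- simulate_study(sim_config(n_subjects = 1), seed = 9)
  clean <- simulate_trial_signals(st, st$trials$trial_id[1])$channels$ecg
  expect_length(autonomic_qc(clean, "ecg"), 0)
  noisy <- channel_signal(clean$samples + rnorm(length(clean$samples), 0, 1),
                          clean$fs, "ecg")
  expect_true("ecg_low_snr" %in% autonomic_qc(noisy, "ecg"))
})
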