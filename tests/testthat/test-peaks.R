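test_that("EMG peaks align to accelerometer peaks, including jittered bursts", {
  # envelope at 100 Hz with 20 bursts of known amplitude
  burst_times <- seq(2, 40, by = 2)
  amps <- seq(0.2, 0.58, by = 0.02)
  env_vals <- rep(0.01, 4500)
  idx <- round(burst_times * 100)
  env_vals[idx] <- amps
  env <- make_envelope(env_vals)

  pk <- detect_movement_peaks(env, burst_times, tol_ms = 100)
  expect_equal(nrow(pk), 20L)
  expect_equal(pk$amplitude, amps)
  expect_equal(attr(pk, "n_unmatched"), 0L)

  # bursts jittered +40 ms from accel peaks still match at 100 ms tolerance
  pk2 <- detect_movement_peaks(env, burst_times - 0.04, tol_ms = 100)
  expect_equal(nrow(pk2), 20L)
  expect_equal(pk2$amplitude, amps)

  # no accel peaks -> empty series, not an error
  pk3 <- detect_movement_peaks(env, numeric(0))
  expect_equal(nrow(pk3), 0L)

  # below-noise-floor windows count as unmatched
  pk4 <- detect_movement_peaks(env, c(burst_times, 55), tol_ms = 100,
                               noise_floor = 0.05)
  expect_equal(nrow(pk4), 20L)
  expect_equal(attr(pk4, "n_unmatched"), 1L)
})

test_that("accelerometer peak detection finds planted transients", {
  fs <- 250
  n <- 60 * fs
  z <- rnorm(n, 0, 0.01)
  at <- seq(3, 57, by = 1.5)
  z[round(at * fs) + 1] <- 2
  times <- detect_accel_peaks(z, fs = fs)
  expect_equal(length(times), length(at))
  expect_equal(times, at, tolerance = 1 / fs)
  expect_equal(detect_accel_peaks(rnorm(n, 0, 0.01), fs = fs), numeric(0))
})

test_that("trim_low_peaks removes exactly floor(frac n), earliest tie first", {
  mk <- function(amp) {
    p <- tibble::tibble(time = seq_along(amp), amplitude = amp,
                        accel_time = seq_along(amp))
    class(p) <- c("movement_peaks", class(tibble::tibble()))
    p
  }
  out <- trim_low_peaks(mk(1:10 / 10), 0.10)
  expect_equal(nrow(out), 9L)
  expect_false(0.1 %in% out$amplitude)

  expect_equal(nrow(trim_low_peaks(mk(1:9 / 10), 0.10)), 9L)  # floor(0.9) = 0

  # tie at the cut: the earliest-time tied peak goes first
  tied <- mk(c(0.5, 0.2, 0.2, 0.9, 0.7, 0.2, 0.8, 0.6, 0.4, 0.3))
  out <- trim_low_peaks(tied, 0.10)
  expect_equal(nrow(out), 9L)
  expect_false(2 %in% out$time)     # time-2 instance of 0.2 dropped
  expect_true(all(c(3, 6) %in% out$time))

  # survivors stay in time order
  expect_true(all(diff(out$time) > 0))
})

test_that("mean peak activation averages amplitudes and flags empty series", {
  mk <- function(amp) tibble::tibble(time = seq_along(amp), amplitude = amp)
  expect_equal(mean_peak_activation(mk(c(0.2, 0.4))), 0.3)
  expect_equal(mean_peak_activation(mk(0.7)), 0.7)
  set.seed(9)
  a <- runif(15)
  expect_equal(mean_peak_activation(mk(a)),
               mean_peak_activation(mk(sample(a))))   # permutation invariant
  empty <- mean_peak_activation(mk(numeric(0)))
  expect_true(is.na(empty))
  expect_equal(attr(empty, "qc"), "emg_no_peaks")
})
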