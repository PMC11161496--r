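test_that("band-pass gain matches the analytic zero-phase Butterworth cascade", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  for (f in c(20, 50, 100, 200, 300, 420)) {
    y <- bandpass_emg(sin(2 * pi * f * t), fs = fs)
    expect_equal(sine_amplitude(y, fs, f), emg_cascade_gain(f, fs),
                 tolerance = 0.01, label = sprintf("gain at %g Hz", f))
  }
})

test_that("band-pass removes DC and attenuates sub-band tones as predicted", {
  fs <- 2000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  y <- bandpass_emg(rep(5, length(t)), fs = fs)
  expect_lt(max(abs(y[1000:(length(y) - 1000)])), 1e-6)

  y1 <- bandpass_emg(sin(2 * pi * 1 * t), fs = fs)
  bound <- emg_cascade_gain(1, fs)
  expect_lt(sine_amplitude(y1, fs, 1), 1.05 * bound)

  expect_error(bandpass_emg(rnorm(100), fs = 800), "Nyquist")
})

test_that("RMS envelope of simple traces is exact", {
  fs <- 2000
  env <- rms_envelope(rep(3, 400), fs = fs, window_ms = 10)
  expect_equal(env$values, rep(3, 20))
  expect_equal(env$fs, 100)
  expect_equal(env$times[1], 0.005)

  alt <- rep(c(2, -2), 200)
  expect_equal(rms_envelope(alt, fs = fs)$values, rep(2, 20))
  expect_equal(rms_envelope(rep(0, 400), fs = fs)$values, rep(0, 20))
})

test_that("compute_mvc equals the brute-force maximum 1-s window mean", {
  fs <- 100
  expect_equal(compute_mvc(rep(2, 5 * fs), fs = fs), 2)
  v <- rep(0, 5 * fs); v[151:250] <- 5
  expect_equal(compute_mvc(v, fs = fs), 5)

  ramp <- seq(0, 1, length.out = 10 * fs)
  expect_equal(compute_mvc(ramp, fs = fs), mvc_brute_force(ramp, fs))
  set.seed(11)
  for (i in 1:5) {
    v <- abs(rnorm(round(runif(1, 1.5, 8) * fs)))
    expect_equal(compute_mvc(v, fs = fs), mvc_brute_force(v, fs))
  }
  expect_error(compute_mvc(rep(1, 50), fs = fs), "shorter than 1 s")
})

test_that("MVC normalization is exact and scale invariant", {
  fs <- 2000
  env <- rms_envelope(rep(1.5, 400), fs = fs)
  expect_equal(normalize_emg(env, 1.5)$values, rep(1, 20))
  expect_error(normalize_emg(env, 0), "positive")

  # common rescaling of raw and MVC traces leaves %MVC unchanged
  set.seed(3)
  raw <- rnorm(6 * fs)
  mvc_raw <- abs(rnorm(3 * fs)) + 0.5
  pct <- function(k) {
    env <- rms_envelope(bandpass_emg(k * raw, fs = fs), fs = fs)
    mvc <- compute_mvc(rms_envelope(bandpass_emg(k * mvc_raw, fs = fs), fs = fs))
    normalize_emg(env, mvc)$values
  }
  expect_equal(pct(1), pct(7.3), tolerance = 1e-10)
})
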