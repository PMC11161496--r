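# Independent analytic oracles used across the signal tests.

# Digital Butterworth magnitude response (bilinear transform with prewarped
# cutoff): the analog prototype evaluated at the warped frequency
# tan(pi f / fs). Closed form, independent of the signal package's filtering.
warp <- function(f, fs) tan(pi * f / fs)

butter_lp_gain <- function(f, fc, order, fs)
  1 / sqrt(1 + (warp(f, fs) / warp(fc, fs))^(2 * order))

butter_hp_gain <- function(f, fc, order, fs)
  1 / sqrt(1 + (warp(fc, fs) / warp(f, fs))^(2 * order))

# Zero-phase (forward-backward) application squares the magnitude response.
emg_cascade_gain <- function(f, fs, band = c(10, 400))
  (butter_hp_gain(f, band[1], 2, fs) * butter_lp_gain(f, band[2], 3, fs))^2

accel_hp_gain <- function(f, fs = 250, fc = 0.5)
  butter_hp_gain(f, fc, 4, fs)^2

# Steady-state amplitude of a sinusoid at frequency f in trace y, estimated
# by quadrature projection over the middle half (avoids filter edge effects).
sine_amplitude <- function(y, fs, f) {
  n <- length(y)
  mid <- seq(floor(n / 4), ceiling(3 * n / 4))
  t <- (mid - 1) / fs
  y <- y[mid]
  2 * sqrt(mean(y * sin(2 * pi * f * t))^2 + mean(y * cos(2 * pi * f * t))^2)
}

# Brute-force MVC oracle: mean over every contiguous 1-s window start.
mvc_brute_force <- function(values, fs) {
  k <- round(fs)
  starts <- seq_len(length(values) - k + 1)
  max(vapply(starts, function(i) mean(values[i:(i + k - 1)]), numeric(1)))
}

# Tucker congruence between two loading vectors.
tucker_phi <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Small synthetic envelope for peak-matching tests.
make_envelope <- function(values, fs = 100) {
  structure(list(values = values, fs = fs,
                 times = ((seq_along(values) - 1) + 0.5) / fs,
                 mvc = 1), class = "emg_envelope")
}
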