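# Accelerometry: resample all axes to a common 250 Hz grid with
# anti-aliasing, remove the gravitational component with a 4th-order 0.5 Hz
# Butterworth high-pass (zero phase), trim filter edge artifacts, and reduce
# to magnitude and total acceleration.

#' Preprocess triaxial accelerometry
#'
#' Brings x/y/z onto a common 250 Hz grid (integer-ratio decimation with
#' anti-aliasing; axes already at the target rate pass through, covering the
#' legacy case of a 250 Hz y axis alongside 2000 Hz x/z), applies a 4th-order
#' 0.5 Hz high-pass Butterworth forward-backward to remove gravity, and trims
#' `trim_s` seconds from each end for filter/resampling artifacts. Total
#' sample loss must stay below 10% of the trial.
#'
#' @param x,y,z `channel_signal` objects for the three axes.
#' @param target_fs Common output rate (samples/second).
#' @param highpass_hz Gravity-removal cutoff in Hz.
#' @param trim_s Seconds trimmed from each end after filtering.
#' @return Tibble with columns `time`, `x`, `y`, `z` at `target_fs`
#'   (attribute `fs`), gravity-free.
#' @export
preprocess_accel <- function(x, y, z, target_fs = 250, highpass_hz = 0.5,
                             trim_s = 1) {
  axes <- list(x = x, y = y, z = z)
  res <- lapply(axes, function(a) {
    stopifnot(inherits(a, "channel_signal"))
    if (a$fs == target_fs) return(a$samples)
    q <- a$fs / target_fs
    if (abs(q - round(q)) > 1e-9 || q < 1)
      abort(sprintf("preprocess_accel: fs %g is not an integer multiple of %g",
                    a$fs, target_fs))
    as.numeric(signal::decimate(a$samples, round(q), ftype = "iir"))
  })
  n <- min(lengths(res))
  res <- lapply(res, function(v) v[seq_len(n)])
  dur <- n / target_fs
  hp <- signal::butter(4, highpass_hz / (target_fs / 2), type = "high")
  # demean before filtering: the high-pass removes DC anyway, and a zero-mean
  # boundary keeps the forward-backward edge transient negligible
  res <- lapply(res, function(v) as.numeric(signal::filtfilt(hp, v - mean(v))))
  ntrim <- round(trim_s * target_fs)
  if (2 * ntrim >= 0.10 * n)
    abort(sprintf(
      "preprocess_accel: edge trim of %g s per side loses %.1f%% of a %.1f s trial (>= 10%% limit)",
      trim_s, 200 * ntrim / n, dur))
  keep <- if (ntrim > 0) (ntrim + 1):(n - ntrim) else seq_len(n)
  out <- tibble(
    time = (keep - 1) / target_fs,
    x = res$x[keep], y = res$y[keep], z = res$z[keep]
  )
  attr(out, "fs") <- target_fs
  out
}

#' Acceleration magnitude
#'
#' Elementwise Euclidean norm of the three axis components.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Non-negative numeric vector `sqrt(x^2 + y^2 + z^2)`.
#' @export
accel_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    abort("accel_magnitude: component length mismatch")
  sqrt(x^2 + y^2 + z^2)
}

#' Total acceleration over a trial
#'
#' Plain sum of the processed acceleration magnitude over the whole signal;
#' units are g-samples at the processed rate (250 Hz by default).
#'
#' @param magnitude Magnitude sequence from [accel_magnitude()].
#' @return Scalar sum.
#' @export
total_acceleration <- function(magnitude) sum(magnitude)
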