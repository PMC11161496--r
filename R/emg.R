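# EMG processing: 10-400 Hz band-pass (2nd-order high-pass cascaded with
# 3rd-order low-pass Butterworth, both applied zero-phase), RMS rectification
# over 10 ms windows, MVC normalization, and movement-peak extraction aligned
# to accelerometer Z peaks.

#' Band-pass filter a raw EMG trace
#'
#' Cascade of a 2nd-order 10 Hz high-pass and a 3rd-order 400 Hz low-pass
#' Butterworth filter. Filters are applied forward-backward (zero phase), so
#' the effective magnitude response is the squared cascade response; peak
#' timing is preserved for alignment with accelerometry.
#'
#' @param x A `channel_signal` (EMG) or numeric vector.
#' @param fs Sampling rate, required if `x` is a bare vector. Must exceed
#'   800 Hz so the 400 Hz band edge is below Nyquist.
#' @param band Band edges in Hz.
#' @return Numeric vector, same length as the input.
#' @export
bandpass_emg <- function(x, fs = NULL, band = c(10, 400)) {
  s <- as_samples(x, fs)
  if (s$fs <= 2 * band[2])
    abort(sprintf("bandpass_emg: band edge %g Hz above Nyquist (fs = %g)",
                  band[2], s$fs))
  hp <- signal::butter(2, band[1] / (s$fs / 2), type = "high")
  lp <- signal::butter(3, band[2] / (s$fs / 2), type = "low")
  y <- signal::filtfilt(hp, s$samples)
  as.numeric(signal::filtfilt(lp, y))
}

#' RMS envelope over contiguous windows
#'
#' Rectifies a filtered EMG trace by taking the root mean square over
#' contiguous, non-overlapping windows (10 ms by default). Envelope samples
#' are timestamped at window centers; a trailing partial window is dropped.
#'
#' @param x Filtered trace (`channel_signal` or numeric).
#' @param fs Sampling rate if `x` is bare.
#' @param window_ms Window length in milliseconds.
#' @return An `emg_envelope`: list with `values` (non-negative), `fs`
#'   (envelope rate, `1000/window_ms` Hz), `times` (window-center seconds)
#'   and `mvc` (NA until normalized).
#' @export
rms_envelope <- function(x, fs = NULL, window_ms = 10) {
  s <- as_samples(x, fs)
  w <- max(1L, round(s$fs * window_ms / 1000))
  n_win <- length(s$samples) %/% w
  if (n_win < 1L) abort("rms_envelope: window longer than trace")
  m <- matrix(s$samples[seq_len(n_win * w)]^2, nrow = w)
  values <- sqrt(colMeans(m))
  structure(
    list(values = values, fs = s$fs / w,
         times = ((seq_len(n_win) - 1) + 0.5) * w / s$fs,
         mvc = NA_real_),
    class = "emg_envelope"
  )
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope: %d windows @ %g Hz%s>\n", length(x$values),
              x$fs, if (is.na(x$mvc)) "" else sprintf(", MVC = %g", x$mvc)))
  invisible(x)
}

#' Maximum voluntary contraction from a rectified MVC trace
#'
#' The MVC constant is the average amplitude of the maximum one-second region:
#' the largest mean over all one-second windows of the rectified envelope.
#'
#' @param env An `emg_envelope` (rectified MVC recording) or numeric vector.
#' @param fs Envelope sampling rate if `env` is bare.
#' @return The MVC constant (same units as the envelope).
#' @export
compute_mvc <- function(env, fs = NULL) {
  if (inherits(env, "emg_envelope")) { values <- env$values; fs <- env$fs }
  else { if (is.null(fs)) abort("fs required"); values <- as.numeric(env) }
  k <- round(fs)
  if (length(values) < k) abort("compute_mvc: trace shorter than 1 s")
  max(zoo::rollmean(values, k, align = "left"))
}

#' Normalize an EMG envelope by MVC
#'
#' Scales the envelope to a fraction of maximum voluntary contraction
#' (multiply by 100 for display as %MVC).
#'
#' @param env An `emg_envelope`.
#' @param mvc MVC constant, > 0, in the envelope's units.
#' @return The envelope with `values` scaled by `1/mvc` and `mvc` recorded.
#' @export
normalize_emg <- function(env, mvc) {
  stopifnot(inherits(env, "emg_envelope"))
  if (!is.numeric(mvc) || length(mvc) != 1L || !is.finite(mvc) || mvc <= 0)
    abort("normalize_emg: mvc must be a positive scalar")
  env$values <- env$values / mvc
  env$mvc <- mvc
  env
}
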