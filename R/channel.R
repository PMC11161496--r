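#' Construct a uniformly sampled channel signal
#'
#' The basic container for one raw trace: a numeric vector of samples with a
#' sampling rate and a modality tag. Units follow the modality convention
#' (EMG and ECG in mV, acceleration in g, EDA in microsiemens).
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in samples/second (> 0).
#' @param modality One of `"emg_flexor"`, `"emg_extensor"`, `"accel_x"`,
#'   `"accel_y"`, `"accel_z"`, `"ecg"`, `"eda"`.
#' @param units Unit label attached to the samples.
#' @return A `channel_signal` object.
#' @export
channel_signal <- function(samples, fs, modality, units = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0L)
    abort("channel_signal: no samples")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("channel_signal: samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort("channel_signal: fs must be a positive scalar")
  modality <- match.arg(modality, MODALITIES)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         modality = modality, units = units),
    class = "channel_signal"
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal %s: %d samples @ %g Hz (%.2f s)%s>\n",
              x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.na(x$units)) "" else paste0(", ", x$units)))
  invisible(x)
}

#' @export
length.channel_signal <- function(x) length(x$samples)

#' Duration of a channel signal in seconds
#' @param x A `channel_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "channel_signal"))
  length(x$samples) / x$fs
}

#' Sample times of a channel signal
#'
#' Times in seconds from trial start; sample `i` (0-based) sits at `i / fs`.
#' @param x A `channel_signal`.
#' @return Numeric vector of times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "channel_signal"))
  (seq_along(x$samples) - 1) / x$fs
}

# Internal: accept a channel_signal or bare numeric + fs.
as_samples <- function(x, fs = NULL) {
  if (inherits(x, "channel_signal")) list(samples = x$samples, fs = x$fs)
  else {
    if (is.null(fs)) abort("fs is required when passing a bare numeric vector")
    list(samples = as.numeric(x), fs = fs)
  }
}
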