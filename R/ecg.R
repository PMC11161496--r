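# Electrocardiography: R-wave detection (detrend, local maxima, 80%-of-window
# thresholding with deduplication), heart rate in beats/minute and RMSSD
# heart-rate variability.

# Remove a least-squares polynomial trend (linear by default).
detrend_signal <- function(v, order = 1) {
  n <- length(v)
  x <- seq_len(n) / n
  X <- cbind(1, stats::poly(x, degree = order, raw = TRUE))
  fit <- stats::lm.fit(X, v)
  as.numeric(fit$residuals)
}

#' Detect R-wave maxima in an ECG trace
#'
#' The trace is detrended (least-squares linear trend by default), candidate
#' local maxima are located, candidates below a global amplitude floor are
#' discarded, then within a 1-second window centered on each candidate,
#' candidates below 80% of the window's highest point are removed. Surviving
#' maxima within `min_sep_ms` collapse to the single largest, guarding against
#' double counting on broad QRS complexes.
#'
#' @param x ECG `channel_signal` or numeric vector.
#' @param fs Sampling rate if `x` is bare.
#' @param window_s Width of the deduplication window (seconds), centered on
#'   each candidate.
#' @param dedup_threshold Fraction of the window maximum below which a
#'   candidate is removed.
#' @param min_sep_ms Minimum separation of retained R waves.
#' @param global_floor Candidates below this fraction of the global
#'   post-detrend maximum are discarded before windowing (automates the
#'   visual rejection of between-beat noise maxima).
#' @param detrend_order Polynomial order of the detrending fit (1 or 2).
#' @return An `r_wave_series`: list with `r_indices` (1-based sample indices,
#'   strictly increasing) and `fs`.
#' @export
detect_r_waves <- function(x, fs = NULL, window_s = 1.0,
                           dedup_threshold = 0.8, min_sep_ms = 250,
                           global_floor = 0.4, detrend_order = 1) {
  s <- as_samples(x, fs)
  if (length(s$samples) < 5 * s$fs)
    abort("detect_r_waves: need at least 5 s of signal")
  v <- detrend_signal(s$samples, order = detrend_order)
  cand <- local_maxima(v)
  cand <- cand[v[cand] > 0]
  cand <- cand[v[cand] >= global_floor * max(v)]
  if (length(cand) >= 2L) {
    half <- round(window_s * s$fs / 2)
    n <- length(v)
    keep <- vapply(cand, function(i) {
      w <- v[max(1L, i - half):min(n, i + half)]
      v[i] >= dedup_threshold * max(w)
    }, logical(1))
    cand <- cand[keep]
  }
  if (length(cand) >= 2L)
    cand <- sort(thin_peaks(cand, v[cand], min_sep_ms / 1000 * s$fs))
  if (length(cand) < 2L)
    abort("detect_r_waves: insufficient R waves")
  structure(list(r_indices = cand, fs = s$fs), class = "r_wave_series")
}

#' @export
print.r_wave_series <- function(x, ...) {
  cat(sprintf("<r_wave_series: %d beats @ %g Hz, BPM %.1f>\n",
              length(x$r_indices), x$fs, bpm(x)))
  invisible(x)
}

#' Heart rate in beats per minute
#'
#' Sampling rate divided by the average samples per beat, times 60.
#'
#' @param r An `r_wave_series` (or integer index vector with `fs` given).
#' @param fs Sampling rate if `r` is bare.
#' @return Beats per minute.
#' @export
bpm <- function(r, fs = NULL) {
  if (inherits(r, "r_wave_series")) { idx <- r$r_indices; fs <- r$fs }
  else { if (is.null(fs)) abort("fs required"); idx <- r }
  if (length(idx) < 2L) abort("bpm: need at least 2 R waves")
  fs / mean(diff(idx)) * 60
}

#' RMSSD heart-rate variability in milliseconds
#'
#' Root mean square of successive differences between inter-beat intervals,
#' a time-domain index of beat-to-beat variability.
#'
#' @inheritParams bpm
#' @return RMSSD in milliseconds.
#' @export
rmssd <- function(r, fs = NULL) {
  if (inherits(r, "r_wave_series")) { idx <- r$r_indices; fs <- r$fs }
  else { if (is.null(fs)) abort("fs required"); idx <- r }
  if (length(idx) < 3L) abort("rmssd: need at least 3 R waves")
  ibi_ms <- diff(idx) / fs * 1000
  sqrt(mean(diff(ibi_ms)^2))
}
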