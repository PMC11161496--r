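# Movement-peak extraction: locate drum-strike transients as accelerometer
# Z peaks, read off the EMG envelope maximum around each, drop the lowest 10%
# of EMG peak amplitudes as noise, and average the remainder.

# Local maxima: samples strictly greater than both neighbors; a flat plateau
# contributes its first sample.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

#' Detect drum-strike peaks on the accelerometer Z axis
#'
#' Local maxima of |z| exceeding a robust data-driven threshold
#' (median + `k_mad` scaled MADs), thinned to a minimum separation keeping the
#' larger peak. Automates the visual alignment check: every retained peak is a
#' candidate movement event.
#'
#' @param accel Processed accelerometry tibble from [preprocess_accel()] (or a
#'   numeric z vector with `fs` given).
#' @param fs Sampling rate if `accel` is a bare vector.
#' @param k_mad Threshold in scaled MADs above the median of |z| (the default
#'   of 8 sits near 5 sigma of Gaussian sensor noise, so a motionless trace
#'   yields no peaks).
#' @param min_sep_ms Minimum separation between retained peaks.
#' @return Numeric vector of peak times in seconds (may be empty).
#' @export
detect_accel_peaks <- function(accel, fs = NULL, k_mad = 8, min_sep_ms = 150) {
  if (is.data.frame(accel)) {
    z <- accel$z
    fs <- attr(accel, "fs")
    t0 <- accel$time[1]
  } else {
    if (is.null(fs)) abort("fs required")
    z <- as.numeric(accel)
    t0 <- 0
  }
  a <- abs(z)
  thr <- median(a) + k_mad * mad(a)
  cand <- local_maxima(a)
  cand <- cand[a[cand] > thr]
  if (length(cand) == 0L) return(numeric(0))
  keep <- thin_peaks(cand, a[cand], min_sep_ms / 1000 * fs)
  t0 + (sort(keep) - 1L) / fs
}

# Greedy amplitude-ordered thinning: keep the largest peak, drop anything
# within min_sep samples of a kept peak.
thin_peaks <- function(idx, amp, min_sep) {
  ord <- order(amp, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  kept
}

#' Match EMG envelope peaks to accelerometer Z peaks
#'
#' For each accelerometer peak, records the maximum of the normalized EMG
#' envelope within an alignment tolerance. Accelerometer peaks with no
#' envelope sample above the noise floor inside the window are dropped and
#' counted as unmatched; duplicate matches to the same envelope sample keep
#' the first event.
#'
#' @param env Normalized `emg_envelope`.
#' @param accel_peak_times Peak times (seconds) from [detect_accel_peaks()].
#' @param tol_ms Alignment tolerance (half-width) in milliseconds.
#' @param noise_floor Envelope values at or below this are not matchable.
#' @return A `movement_peaks` tibble with columns `time` (envelope peak time),
#'   `amplitude` (envelope value, fraction of MVC) and `accel_time`; attribute
#'   `n_unmatched` counts dropped accelerometer peaks.
#' @export
detect_movement_peaks <- function(env, accel_peak_times, tol_ms = 100,
                                  noise_floor = 0) {
  stopifnot(inherits(env, "emg_envelope"))
  tol <- tol_ms / 1000
  rows <- list(); used <- integer(0); unmatched <- 0L
  for (tp in accel_peak_times) {
    in_win <- which(env$times >= tp - tol & env$times <= tp + tol)
    if (length(in_win) == 0L) { unmatched <- unmatched + 1L; next }
    j <- in_win[which.max(env$values[in_win])]
    if (env$values[j] <= noise_floor || j %in% used) {
      unmatched <- unmatched + 1L
      next
    }
    used <- c(used, j)
    rows[[length(rows) + 1L]] <-
      tibble(time = env$times[j], amplitude = env$values[j], accel_time = tp)
  }
  out <- if (length(rows)) bind_rows(rows) |> arrange(.data$time)
         else tibble(time = numeric(), amplitude = numeric(),
                     accel_time = numeric())
  attr(out, "n_unmatched") <- unmatched
  class(out) <- c("movement_peaks", class(out))
  out
}

#' Drop the lowest-amplitude fraction of movement peaks
#'
#' Removes `floor(frac * n)` peaks of smallest EMG amplitude (noise control).
#' Ties at the cut are broken by a stable (amplitude, time) sort: the
#' earliest-time tied peak is dropped first. Time ordering of the survivors
#' is preserved.
#'
#' @param peaks A `movement_peaks` tibble.
#' @param frac Fraction in `[0, 1)` to drop.
#' @return The trimmed `movement_peaks` tibble.
#' @export
trim_low_peaks <- function(peaks, frac = 0.10) {
  stopifnot(frac >= 0, frac < 1)
  n_drop <- floor(frac * nrow(peaks))
  if (n_drop == 0L) return(peaks)
  ord <- order(peaks$amplitude, peaks$time)   # stable: earliest tied first
  drop <- ord[seq_len(n_drop)]
  out <- peaks[-drop, , drop = FALSE] |> arrange(.data$time)
  attr(out, "n_unmatched") <- attr(peaks, "n_unmatched")
  class(out) <- c("movement_peaks", class(tibble()))
  out
}

#' Mean movement-peak EMG activation
#'
#' Arithmetic mean of the retained peak amplitudes (fraction of MVC). Flexor
#' and extensor are processed independently and their two means averaged at
#' the trial level (see [derive_trial_measures()]).
#'
#' @param peaks A `movement_peaks` tibble (after [trim_low_peaks()]).
#' @return Mean amplitude, or `NA` (with attribute `qc = "emg_no_peaks"`) if
#'   no peaks were retained.
#' @export
mean_peak_activation <- function(peaks) {
  if (nrow(peaks) == 0L) {
    out <- NA_real_
    attr(out, "qc") <- "emg_no_peaks"
    return(out)
  }
  mean(peaks$amplitude)
}
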