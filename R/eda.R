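# Electrodermal activity: tonic level as the trial mean, baselined against
# the subject's listen-only trial; plus automated quality flags replacing
# visual inspection of EDA ceiling effects and ECG signal-to-noise.

#' Tonic electrodermal level of a trial
#'
#' The tonic response is the arithmetic mean of the EDA trace over the
#' one-minute trial (no phasic/tonic decomposition).
#'
#' @param x EDA `channel_signal` or numeric vector (microsiemens).
#' @return Mean level in microsiemens.
#' @export
tonic_eda <- function(x) {
  s <- if (inherits(x, "channel_signal")) x$samples else as.numeric(x)
  mean(s)
}

#' Baseline-correct a tonic EDA value
#'
#' Subtracts the subject's listen-only tonic level from a playing-trial tonic
#' level; the difference may be negative. A missing baseline yields a missing
#' value carrying a QC flag rather than a silent zero.
#'
#' @param trial_tonic Tonic level of the playing trial.
#' @param listen_tonic Tonic level of the same subject's listen-only trial.
#' @return `trial_tonic - listen_tonic`, or `NA` with attribute
#'   `qc = "eda_no_baseline"` when the baseline is missing.
#' @export
baseline_correct_eda <- function(trial_tonic, listen_tonic) {
  if (is.null(listen_tonic) || length(listen_tonic) == 0L || is.na(listen_tonic)) {
    out <- NA_real_
    attr(out, "qc") <- "eda_no_baseline"
    return(out)
  }
  trial_tonic - listen_tonic
}

#' Automated quality flags for autonomic traces
#'
#' Screens a raw trace for the failure modes that led to per-modality
#' exclusions: EDA ceiling saturation (a sustained fraction of samples pinned
#' at the range maximum), flat EDA (variance below floor), and low ECG
#' signal-to-noise (QRS amplitude against robust residual noise after
#' detrending). Flagged trials are excluded from the corresponding outcome
#' only, never from the whole dataset.
#'
#' @param x `channel_signal` or numeric trace.
#' @param modality `"eda"` or `"ecg"`.
#' @param ceiling_frac Flag EDA if at least this fraction of samples lies
#'   within `ceiling_eps` of the observed maximum.
#' @param ceiling_eps Closeness to the maximum, as a fraction of the range.
#' @param flat_var Variance floor below which EDA is flagged flat.
#' @param snr_min Minimum acceptable ECG peak-amplitude/noise ratio.
#' @return Character vector of flags (possibly empty): `"eda_ceiling"`,
#'   `"eda_flat"`, `"ecg_low_snr"`.
#' @export
autonomic_qc <- function(x, modality = c("eda", "ecg"),
                         ceiling_frac = 0.05, ceiling_eps = 0.01,
                         flat_var = 1e-6, snr_min = 8) {
  modality <- match.arg(modality)
  v <- if (inherits(x, "channel_signal")) x$samples else as.numeric(x)
  flags <- character(0)
  if (modality == "eda") {
    rng <- range(v)
    span <- diff(rng)
    if (span <= 0 || var(v) < flat_var) flags <- c(flags, "eda_flat")
    if (span > 0) {
      near_max <- mean(v >= rng[2] - ceiling_eps * span)
      if (near_max >= ceiling_frac) flags <- c(flags, "eda_ceiling")
    }
  } else {
    d <- detrend_signal(v)
    noise <- mad(d)
    amp <- as.numeric(quantile(d, 0.999))
    if (noise <= 0 || amp / noise < snr_min) flags <- c(flags, "ecg_low_snr")
  }
  flags
}
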