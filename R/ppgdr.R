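#' @useDynLib ppgcsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Zero-phase IIR filtering with odd-reflection padding. signal::filtfilt alone
# leaves large edge transients at low normalized cutoffs; reflecting about the
# endpoints (scipy-style) before the forward-backward pass suppresses them.
zerophase_filter <- function(flt, x, padlen) {
  n <- length(x)
  padlen <- max(1L, min(as.integer(padlen), n - 1L))
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(padlen + 1L):(padlen + n)]
}

#' High-pass filter a PPG recording
#'
#' Removes slowly varying baseline modulation (vasomotion, drift) below the
#' breathing band. A 4th-order Butterworth high-pass is applied
#' forward-backward (zero phase) so that event timing is not shifted.
#'
#' @param ppg A \code{ppg_recording}.
#' @param cutoff_hz Cutoff frequency in Hz; default 0.15, below the adult
#'   breathing range of 0.2-0.33 Hz.
#' @return Numeric vector, same length as the input samples.
#' @export
highpass <- function(ppg, cutoff_hz = 0.15) {
  stopifnot(inherits(ppg, "ppg_recording"))
  if (ppg$fs <= 2 * cutoff_hz)
    stop("sampling rate too low for the requested cutoff")
  flt <- signal::butter(4, cutoff_hz / (ppg$fs / 2), type = "high")
  padlen <- ceiling(3 * ppg$fs / cutoff_hz)
  zerophase_filter(flt, ppg$samples, padlen)
}

#' Upper peak envelope of a pulsatile signal
#'
#' Detects pulse-wise local maxima (minimum separation
#' \code{min_peak_dist_ms}) and interpolates between them with a monotone
#' cubic spline, sampled back at the original rate. Monotone (Fritsch-Carlson)
#' interpolation avoids the overshoot a plain cubic spline would add between
#' beats of different amplitude. Beyond the first/last peak the envelope is
#' held constant.
#'
#' @param x Filtered PPG samples.
#' @param fs Sampling rate in Hz.
#' @param min_peak_dist_ms Minimum pulse separation in milliseconds.
#' @return Numeric envelope, same length as \code{x}.
#' @export
peak_envelope <- function(x, fs, min_peak_dist_ms = 250) {
  pk <- find_peaks(x, min_dist = max(1L, round(min_peak_dist_ms / 1000 * fs)))
  if (length(pk) >= 2L) {
    # keep pulse-wise maxima only: between-beat ripple has tiny topographic
    # prominence compared with cardiac pulses (even vasoconstricted ones)
    prom <- peak_prominence(x, pk)
    pk <- pk[prom > 0.1 * stats::quantile(prom, 0.9, names = FALSE)]
  }
  if (length(pk) < 2L)
    stop("degenerate signal: fewer than two pulse maxima detected")
  f <- stats::splinefun(pk, x[pk], method = "monoH.FC")
  idx <- seq_along(x)
  env <- f(pmin(pmax(idx, pk[1]), pk[length(pk)]))
  env
}

#' Normalize a peak envelope into the PPGDR signal
#'
#' Subtracts a short centered moving average (removing residual baseline) and
#' divides by a longer centered moving interquartile range (normalizing
#' steady-state amplitude changes, e.g. probe coupling or perfusion level).
#' Windows shrink at the recording edges. The IQR divisor is floored at a
#' small epsilon so a locally constant envelope yields 0, never NaN/Inf.
#'
#' @param env Envelope samples.
#' @param fs Sampling rate in Hz.
#' @param ma_window_s Moving-average window in seconds (default 6).
#' @param iqr_window_s Moving-IQR window in seconds (default 30).
#' @return Numeric PPGDR vector, same length as \code{env}.
#' @export
normalize_envelope <- function(env, fs, ma_window_s = 6, iqr_window_s = 30) {
  if (iqr_window_s <= ma_window_s)
    stop("iqr_window_s must exceed ma_window_s")
  if (length(env) < iqr_window_s * fs)
    stop("degenerate signal: shorter than the IQR normalization window")
  h_ma <- max(1L, round(ma_window_s * fs / 2))
  h_iqr <- max(1L, round(iqr_window_s * fs / 2))
  ma <- roll_mean_cpp(env, h_ma)
  q75 <- roll_quantile_cpp(env, h_iqr, 0.75)
  q25 <- roll_quantile_cpp(env, h_iqr, 0.25)
  iqr <- q75 - q25
  eps <- max(1e-6 * stats::median(abs(env)), 1e-12)
  (env - ma) / pmax(iqr, eps)
}

#' Extract the PPG-derived respiratory effort (PPGDR) signal
#'
#' Composition of \code{\link{highpass}}, \code{\link{peak_envelope}} and
#' \code{\link{normalize_envelope}}: the pulse-amplitude modulation imposed on
#' finger PPG by intrathoracic pressure swings is demodulated into a
#' normalized surrogate of respiratory effort. During central events
#' (no effort) the PPGDR flattens; during obstructive events (effort against
#' a closed airway) it keeps oscillating.
#'
#' @param ppg A \code{ppg_recording}.
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{ppgdr_signal}: list with \code{values}
#'   (same length as the PPG), \code{fs} and \code{derived_from}.
#' @export
extract_ppgdr <- function(ppg, config = pipeline_config()) {
  filt <- highpass(ppg, config$hp_cutoff_hz)
  env <- peak_envelope(filt, ppg$fs, config$min_peak_dist_ms)
  vals <- normalize_envelope(env, ppg$fs, config$env_ma_window_s,
                             config$env_iqr_window_s)
  structure(list(values = vals, fs = ppg$fs, derived_from = ppg$patient_id),
            class = "ppgdr_signal")
}

#' @export
print.ppgdr_signal <- function(x, ...) {
  cat(sprintf("<ppgdr_signal> from %s: %d samples @ %g Hz\n",
              x$derived_from, length(x$values), x$fs))
  invisible(x)
}
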