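#' Pipeline configuration
#'
#' Collects every fixed parameter of the CSA detection pipeline in one place.
#' Defaults are the operating point the method was designed at; all are
#' overridable for sensitivity analyses.
#'
#' @param hp_cutoff_hz High-pass cutoff (Hz) removing slow PPG baseline drift
#'   while leaving adult breathing frequencies (0.2-0.33 Hz) untouched.
#' @param env_ma_window_s Moving-average window (s) subtracted from the peak
#'   envelope to remove residual baseline fluctuation.
#' @param env_iqr_window_s Moving interquartile-range window (s) dividing the
#'   envelope to normalize steady-state amplitude changes.
#' @param feature_windows_s Sliding-window lengths (s) for range features; the
#'   two largest are also used for IQR, variance and peak-count features.
#' @param stride_s Stride (s) of the sliding-window feature pass.
#' @param min_peak_dist_ms Minimum separation (ms) between detected local
#'   maxima, for both cardiac beats and PPGDR breathing peaks.
#' @param irr_interval_frac Fraction of the mean of two neighboring
#'   peak-to-peak intervals above which their difference marks them irregular.
#' @param event_irr_frac Maximum tolerated fraction of irregular intervals
#'   inside an event before the event is rejected (strict >).
#' @param erp_cutoff Maximum tolerated event rejection proportion (ERP) per
#'   patient before the patient is rejected (strict >).
#' @param match_gap_s Maximum gap (s) by which a ground-truth annotation may
#'   precede a detected event and still be matched to it.
#' @param vaso_prominence_frac Trough prominence, as a fraction of the rolling
#'   median envelope level, above which a vasoconstriction is flagged.
#' @param vaso_recovery_frac Envelope level, as a fraction of local baseline,
#'   below which samples around a detected trough belong to the zone.
#' @param vaso_baseline_window_s Rolling-median window (s) defining the local
#'   envelope baseline for vasoconstriction detection.
#' @param n_trees Number of bagged trees.
#' @param max_splits Maximum number of internal splits per tree.
#' @param fp_cost Cost of calling an obstructive event central, relative to
#'   the opposite error; shifts the decision threshold to
#'   \code{fp_cost/(1+fp_cost)} and keeps CSA from being over-called.
#' @param rng_seed Integer seed governing all stochastic steps.
#'
#' @return An object of class \code{ppgcsa_config} (a named list).
#' @export
pipeline_config <- function(hp_cutoff_hz = 0.15,
                            env_ma_window_s = 6,
                            env_iqr_window_s = 30,
                            feature_windows_s = c(5, 7, 11, 21),
                            stride_s = 1,
                            min_peak_dist_ms = 250,
                            irr_interval_frac = 0.20,
                            event_irr_frac = 0.20,
                            erp_cutoff = 0.3,
                            match_gap_s = 10,
                            vaso_prominence_frac = 0.5,
                            vaso_recovery_frac = 0.7,
                            vaso_baseline_window_s = 120,
                            n_trees = 30,
                            max_splits = 150,
                            fp_cost = 2.5,
                            rng_seed = 20230112L) {
  cfg <- list(
    hp_cutoff_hz = hp_cutoff_hz,
    env_ma_window_s = env_ma_window_s,
    env_iqr_window_s = env_iqr_window_s,
    feature_windows_s = sort(feature_windows_s),
    stride_s = stride_s,
    min_peak_dist_ms = min_peak_dist_ms,
    irr_interval_frac = irr_interval_frac,
    event_irr_frac = event_irr_frac,
    erp_cutoff = erp_cutoff,
    match_gap_s = match_gap_s,
    vaso_prominence_frac = vaso_prominence_frac,
    vaso_recovery_frac = vaso_recovery_frac,
    vaso_baseline_window_s = vaso_baseline_window_s,
    n_trees = as.integer(n_trees),
    max_splits = as.integer(max_splits),
    fp_cost = fp_cost,
    rng_seed = as.integer(rng_seed)
  )
  thresholds <- c(cfg$hp_cutoff_hz, cfg$env_ma_window_s, cfg$env_iqr_window_s,
                  cfg$feature_windows_s, cfg$stride_s, cfg$min_peak_dist_ms,
                  cfg$irr_interval_frac, cfg$event_irr_frac, cfg$match_gap_s,
                  cfg$n_trees, cfg$max_splits, cfg$fp_cost)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all pipeline thresholds must be positive and finite")
  if (cfg$erp_cutoff <= 0 || cfg$erp_cutoff >= 1)
    stop("erp_cutoff must lie in (0, 1)")
  if (cfg$env_iqr_window_s <= cfg$env_ma_window_s)
    stop("env_iqr_window_s must exceed env_ma_window_s")
  class(cfg) <- "ppgcsa_config"
  cfg
}

#' Construct a PPG recording
#'
#' The sole physiological input of the pipeline: a raw finger PPG waveform in
#' arbitrary units at a fixed sampling rate.
#'
#' @param samples Numeric vector of PPG samples (arbitrary units).
#' @param fs Sampling rate in Hz (> 0; the method assumes >= 25 Hz).
#' @param patient_id Identifier string.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class \code{ppg_recording}.
#' @export
ppg_recording <- function(samples, fs, patient_id = "anon", start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (any(!is.finite(samples))) stop("all PPG samples must be finite")
  structure(
    list(patient_id = as.character(patient_id), fs = fs,
         samples = samples, start_time = start_time),
    class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> patient %s: %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a PPG recording in seconds
#' @param x A \code{ppg_recording}.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) length(x$samples) / x$fs

EVENT_SOURCES <- c("pat_hsat", "expert", "local")
EVENT_TYPES <- c("central", "obstructive", "mixed", "unlabeled")

#' Construct a respiratory-event table
#'
#' Events are half-open intervals \code{[start, end)} in seconds from the
#' recording start. Two events overlap iff
#' \code{a$start < b$end && b$start < a$end}.
#'
#' @param start,end Numeric vectors of event boundaries in seconds.
#' @param source Event provenance: \code{"pat_hsat"} (the HSAT detector),
#'   \code{"expert"} or \code{"local"} (PSG scorings).
#' @param type Event type: \code{"central"}, \code{"obstructive"},
#'   \code{"mixed"} or \code{"unlabeled"}.
#' @param rejected Logical rejection flags (quality layer; default FALSE).
#' @return A data.frame of class \code{respiratory_events}, sorted by start,
#'   with columns \code{event_id, start, end, source, type, rejected}.
#' @export
respiratory_events <- function(start, end, source = "pat_hsat",
                               type = "unlabeled", rejected = FALSE) {
  n <- length(start)
  ev <- data.frame(
    event_id = character(n), start = as.numeric(start), end = as.numeric(end),
    source = rep_len(as.character(source), n),
    type = rep_len(as.character(type), n),
    rejected = rep_len(as.logical(rejected), n),
    stringsAsFactors = FALSE)
  if (any(!is.finite(ev$start)) || any(!is.finite(ev$end)))
    stop("event boundaries must be finite")
  if (any(ev$end <= ev$start)) stop("event end must exceed start")
  if (!all(ev$source %in% EVENT_SOURCES))
    stop("unknown event source; expected one of ",
         paste(EVENT_SOURCES, collapse = ", "))
  if (!all(ev$type %in% EVENT_TYPES))
    stop("unknown event type; expected one of ",
         paste(EVENT_TYPES, collapse = ", "))
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  ev$event_id <- sprintf("%s_%04d", ev$source, seq_len(n))
  rownames(ev) <- NULL
  class(ev) <- c("respiratory_events", "data.frame")
  ev
}

#' Test interval overlap under the half-open convention
#'
#' @param a_start,a_end,b_start,b_end Interval boundaries (vectorized).
#' @return Logical vector: TRUE where \code{[a_start,a_end)} and
#'   \code{[b_start,b_end)} share a point.
#' @export
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

#' Bundle one patient's data
#'
#' @param recording A \code{ppg_recording}.
#' @param pat_events HSAT-detected events (\code{respiratory_events}).
#' @param tst_hours Total sleep time in hours (> 0), the AHI denominator.
#' @param expert_events,local_events Optional PSG annotation tables used for
#'   training-label construction.
#' @param true_cahi Optional ground-truth central AHI (simulator bookkeeping).
#' @return An object of class \code{patient_record}.
#' @export
patient_record <- function(recording, pat_events, tst_hours,
                           expert_events = NULL, local_events = NULL,
                           true_cahi = NA_real_) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (!is.numeric(tst_hours) || tst_hours <= 0)
    stop("tst_hours must be positive")
  dur <- recording_duration(recording)
  for (ev in list(pat_events, expert_events, local_events)) {
    if (!is.null(ev) && nrow(ev) &&
        (min(ev$start) < 0 || max(ev$end) > dur + 1e-9))
      stop("event times must lie within the recording duration")
  }
  structure(
    list(recording = recording, pat_events = pat_events,
         expert_events = expert_events, local_events = local_events,
         tst_hours = tst_hours, true_cahi = true_cahi),
    class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %.0f s PPG, %d HSAT events, TST %.2f h\n",
              x$recording$patient_id, recording_duration(x$recording),
              nrow(x$pat_events), x$tst_hours))
  invisible(x)
}
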