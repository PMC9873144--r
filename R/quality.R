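#' Detect cardiac beats in a PPG recording
#'
#' Beats are local maxima of the high-pass-filtered PPG with minimum
#' separation \code{min_peak_dist_ms}; candidate peaks far below the local
#' pulse amplitude (under 30\% of a rolling median of peak heights) are
#' dropped as noise.
#'
#' @param ppg A \code{ppg_recording}.
#' @param config A \code{\link{pipeline_config}}.
#' @return Numeric vector of beat times in seconds, increasing.
#' @export
detect_beats <- function(ppg, config = pipeline_config()) {
  x <- highpass(ppg, config$hp_cutoff_hz)
  pk <- find_peaks(x, max(1L, round(config$min_peak_dist_ms / 1000 * ppg$fs)))
  if (length(pk) < 3L) stop("degenerate signal: too few beats")
  h <- x[pk]
  k <- min(15L, length(h) - (1 - length(h) %% 2)) # odd, <= length
  ref <- if (k >= 3) stats::runmed(h, k) else rep(stats::median(h), length(h))
  keep <- h > 0.3 * ref
  (pk[keep] - 1) / ppg$fs
}

#' Detect vasoconstriction-affected zones
#'
#' Strong peripheral vasoconstrictions collapse the PPG pulse amplitude and
#' leave low signal-to-noise episodes that normalization cannot rescue. The
#' pulse-amplitude trend (peak envelope of the filtered PPG, low-pass
#' filtered at 0.05 Hz to remove breathing and residual baseline) is searched
#' for troughs whose prominence exceeds \code{vaso_prominence_frac} of a
#' rolling-median baseline; each trough is expanded to the surrounding region
#' where the trend stays below \code{vaso_recovery_frac} of that baseline.
#'
#' @param ppg A \code{ppg_recording} of at least 60 s.
#' @param config A \code{\link{pipeline_config}}.
#' @return data.frame with columns \code{start, end} (seconds, half-open),
#'   possibly empty, ordered and non-overlapping.
#' @export
detect_vasoconstrictions <- function(ppg, config = pipeline_config()) {
  if (recording_duration(ppg) < 60) stop("recording must be at least 60 s")
  fs <- ppg$fs
  filt <- highpass(ppg, config$hp_cutoff_hz)
  env <- peak_envelope(filt, fs, config$min_peak_dist_ms)
  lp <- signal::butter(2, 0.05 / (fs / 2), type = "low")
  trend <- zerophase_filter(lp, env, ceiling(3 * fs / 0.05))
  half_bl <- max(1L, round(config$vaso_baseline_window_s * fs / 2))
  baseline <- roll_quantile_cpp(trend, half_bl, 0.5)
  troughs <- find_peaks(-trend, min_dist = round(5 * fs))
  if (!length(troughs)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  prom <- peak_prominence(-trend, troughs)
  sig <- troughs[prom > config$vaso_prominence_frac * baseline[troughs] &
                   trend[troughs] < config$vaso_recovery_frac *
                     baseline[troughs]]
  if (!length(sig)) return(data.frame(start = numeric(0), end = numeric(0)))
  below <- trend < config$vaso_recovery_frac * baseline
  zones <- lapply(sig, function(p) {
    lo <- p
    while (lo > 1L && below[lo - 1L]) lo <- lo - 1L
    hi <- p
    n <- length(below)
    while (hi < n && below[hi + 1L]) hi <- hi + 1L
    c((lo - 1) / fs, hi / fs)
  })
  z <- do.call(rbind, zones)
  z <- unique(data.frame(start = z[, 1], end = z[, 2]))
  z <- z[order(z$start), , drop = FALSE]
  # merge overlaps
  if (nrow(z) > 1L) {
    merged <- z[1, , drop = FALSE]
    for (i in 2:nrow(z)) {
      j <- nrow(merged)
      if (z$start[i] <= merged$end[j]) {
        merged$end[j] <- max(merged$end[j], z$end[i])
      } else merged <- rbind(merged, z[i, ])
    }
    z <- merged
  }
  rownames(z) <- NULL
  z
}

#' Mask window-feature rows falling inside zones
#'
#' Feature windows whose center-second lies in a vasoconstriction zone are
#' excluded from event aggregation.
#'
#' @param series A \code{window_features} data.frame.
#' @param zones data.frame with \code{start, end} columns (half-open).
#' @return Logical vector, TRUE where the row is masked.
#' @export
zone_mask <- function(series, zones) {
  in_interval(series$center_s, zones)
}

#' Flag irregular peak-to-peak intervals
#'
#' Two neighboring intervals form an irregular pair when the absolute
#' difference between them exceeds \code{frac} of their mean. An interval is
#' irregular if any pair it participates in is irregular (the first and last
#' interval have only one pair to be judged on). Irregular intervals signal
#' motion artifact or cardiac arrhythmia that corrupts the PPGDR.
#'
#' @param beat_times Numeric beat times in seconds (>= 3 beats).
#' @param frac Relative difference threshold (default 0.20, strict >).
#' @return Logical vector with one flag per interval
#'   (\code{length(beat_times) - 1}).
#' @export
irregular_intervals <- function(beat_times, frac = 0.20) {
  d <- diff(beat_times)
  m <- length(d)
  if (m < 2L) stop("need at least two peak-to-peak intervals")
  pair_irr <- abs(diff(d)) > frac * (d[-m] + d[-1L]) / 2
  irr <- logical(m)
  irr[-m] <- irr[-m] | pair_irr
  irr[-1L] <- irr[-1L] | pair_irr
  irr
}

#' Reject events with too many irregular intervals
#'
#' An interval belongs to an event when its midpoint lies in
#' \code{[start, end)}. An event is rejected when more than
#' \code{threshold} (strictly) of its intervals are irregular, or when it
#' contains no interval at all (no evidence of usable signal).
#'
#' @param events A \code{respiratory_events} table.
#' @param beat_times Beat times in seconds.
#' @param irregular Logical per-interval irregularity mask
#'   (\code{\link{irregular_intervals}}).
#' @param threshold Maximum tolerated irregular fraction (default 0.20).
#' @param extra_rejected Optional logical per event: additional rejection
#'   reasons (e.g. feature-degenerate events), OR-ed in before computing ERP.
#' @return List: \code{events} (rejected flags set), \code{irr_frac}
#'   (per-event irregular fraction, NA when no intervals), \code{erp}.
#' @export
reject_events <- function(events, beat_times, irregular, threshold = 0.20,
                          extra_rejected = NULL) {
  mids <- (beat_times[-length(beat_times)] + beat_times[-1L]) / 2
  irr_frac <- rep(NA_real_, nrow(events))
  rej <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    inside <- mids >= events$start[i] & mids < events$end[i]
    if (!any(inside)) {
      rej[i] <- TRUE
    } else {
      irr_frac[i] <- mean(irregular[inside])
      rej[i] <- irr_frac[i] > threshold
    }
  }
  if (!is.null(extra_rejected)) rej <- rej | extra_rejected
  events$rejected <- rej
  erp <- if (nrow(events)) mean(rej) else 0
  list(events = events, irr_frac = irr_frac, erp = erp)
}

#' Patient-level rejection by event rejection proportion
#'
#' @param erp Event rejection proportion in [0, 1].
#' @param cutoff Maximum tolerated ERP (default 0.3; strict >).
#' @return TRUE when the patient must be rejected.
#' @export
reject_patient <- function(erp, cutoff = 0.3) {
  stopifnot(erp >= 0, erp <= 1)
  erp > cutoff
}

#' Full quality assessment for one recording
#'
#' Runs the three rejection layers in order: vasoconstriction zone detection,
#' irregular-interval event rejection (plus feature-degeneracy), and
#' ERP-based patient rejection.
#'
#' @param ppg A \code{ppg_recording}.
#' @param events The patient's detected respiratory events.
#' @param config A \code{\link{pipeline_config}}.
#' @param degenerate Optional logical per event: feature-degenerate flags.
#' @return An object of class \code{quality_report}: list with
#'   \code{vaso_zones}, \code{beat_times}, \code{irregular_mask},
#'   \code{irr_frac}, \code{events}, \code{erp}, \code{patient_rejected}.
#' @export
quality_report <- function(ppg, events, config = pipeline_config(),
                           degenerate = NULL) {
  zones <- detect_vasoconstrictions(ppg, config)
  beats <- detect_beats(ppg, config)
  irr <- irregular_intervals(beats, config$irr_interval_frac)
  rr <- reject_events(events, beats, irr, config$event_irr_frac,
                      extra_rejected = degenerate)
  structure(list(vaso_zones = zones, beat_times = beats,
                 irregular_mask = irr, irr_frac = rr$irr_frac,
                 events = rr$events, erp = rr$erp,
                 patient_rejected = reject_patient(rr$erp, config$erp_cutoff)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> %d vaso zone(s), %d/%d events rejected (ERP %.2f)%s\n",
    nrow(x$vaso_zones), sum(x$events$rejected), nrow(x$events), x$erp,
    if (x$patient_rejected) " -- PATIENT REJECTED" else ""))
  invisible(x)
}
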