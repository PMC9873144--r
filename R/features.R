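# Scalar window features: a flat PPGDR segment (no breathing effort) has
# near-zero range/IQR/variance and few or no breathing peaks.
window_scalar_feats <- function(w) {
  c(range = max(w) - min(w),
    iqr = unname(diff(stats::quantile(w, c(0.25, 0.75), names = FALSE))),
    var = mean((w - mean(w))^2)) # population variance
}

#' Sliding-window features over a PPGDR signal
#'
#' Slides windows of the configured lengths over the PPGDR with a 1 s stride
#' and ascribes each window's features to the one-second interval at its
#' center. Range is computed for all window lengths; interquartile range,
#' population variance and breathing-peak count for the two longest. Windows
#' are truncated where they extend past the recording edges.
#'
#' @param ppgdr A \code{ppgdr_signal}.
#' @param config A \code{\link{pipeline_config}}.
#' @return A data.frame of class \code{window_features}: one row per
#'   center-second, columns \code{center_s} (window-center time) plus
#'   \code{range_5, range_7, range_11, range_21, iqr_11, iqr_21, var_11,
#'   var_21, npeaks_11, npeaks_21}.
#' @export
sliding_features <- function(ppgdr, config = pipeline_config()) {
  x <- ppgdr$values
  fs <- ppgdr$fs
  dur <- length(x) / fs
  wins <- config$feature_windows_s
  if (dur < max(wins)) stop("signal shorter than the largest feature window")
  long2 <- utils::tail(wins, 2) # IQR/var/peaks on the two longest windows
  centers <- seq(0.5, dur - 0.5, by = config$stride_s)
  min_dist <- max(1L, round(config$min_peak_dist_ms / 1000 * fs))
  rows <- lapply(centers, function(ct) {
    out <- numeric(0)
    for (w in wins) {
      lo <- max(1L, floor((ct - w / 2) * fs) + 1L)
      hi <- min(length(x), ceiling((ct + w / 2) * fs))
      seg <- x[lo:hi]
      out[paste0("range_", w)] <- max(seg) - min(seg)
      if (w %in% long2) {
        sf <- window_scalar_feats(seg)
        out[paste0("iqr_", w)] <- sf["iqr"]
        out[paste0("var_", w)] <- sf["var"]
        out[paste0("npeaks_", w)] <- length(find_peaks(seg, min_dist))
      }
    }
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  ord <- c(paste0("range_", wins), paste0("iqr_", long2),
           paste0("var_", long2), paste0("npeaks_", long2))
  df <- df[, ord, drop = FALSE]
  df <- cbind(center_s = centers, df)
  class(df) <- c("window_features", "data.frame")
  df
}

#' Count PPGDR breathing peaks in a window
#'
#' Local maxima with a minimum separation of \code{min_dist_ms}; an absence
#' of maxima over a window suggests absent breathing effort.
#'
#' @param window Numeric PPGDR segment.
#' @param fs Sampling rate in Hz.
#' @param min_dist_ms Minimum peak separation in milliseconds.
#' @return Integer peak count.
#' @export
detect_ppgdr_peaks <- function(window, fs, min_dist_ms = 250) {
  if (!length(window)) stop("window must be non-empty")
  length(find_peaks(window, max(1L, round(min_dist_ms / 1000 * fs))))
}

SCALAR_SERIES <- c("range_5", "range_7", "range_11", "range_21",
                   "iqr_11", "iqr_21", "var_11", "var_21")
PEAK_SERIES <- c("npeaks_11", "npeaks_21")
SCALAR_AGGS <- c("min", "low3", "p10", "p25")
PEAK_AGGS <- c("min", "n0", "n1", "n2", "p0", "p1", "p2")

#' Names of the aggregated per-event feature vector, in frozen order
#'
#' 8 scalar window series x {min, mean of lowest 3, 10th pct, 25th pct} plus
#' 2 peak-count series x {min, counts and proportions of windows with 0/1/2
#' peaks} = 46 features. The ordering is part of the model contract: trained
#' models store its hash and refuse mismatched inputs.
#'
#' @return Character vector of length 46.
#' @export
feature_names <- function() {
  c(as.vector(outer(SCALAR_SERIES, SCALAR_AGGS, paste, sep = "_")),
    as.vector(outer(PEAK_SERIES, PEAK_AGGS, paste, sep = "_")))
}

#' Version hash of the feature-vector layout
#' @return Character scalar identifying the frozen feature ordering.
#' @export
feature_version <- function() {
  nm <- feature_names()
  sprintf("ppgcsa-fv1-%d-%s", length(nm),
          format(sum(utf8ToInt(paste(nm, collapse = "|")) *
                       seq_len(nchar(paste(nm, collapse = "|")))) %% 100000))
}

#' Aggregate window features over one respiratory event
#'
#' Selects the window-feature rows whose center-second lies inside the event
#' interval \code{[start, end)} (minus any masked seconds, e.g.
#' vasoconstriction zones) and aggregates them: minimum, mean of the lowest
#' three values and 10th/25th percentiles for scalar series; minimum plus
#' counts and proportions of windows with zero, one and two peaks for the
#' peak-count series. Fewer than three usable windows cannot support the
#' lowest-three mean, so the event is flagged degenerate.
#'
#' @param start,end Event boundaries in seconds.
#' @param series A \code{window_features} data.frame.
#' @param mask Optional logical vector parallel to \code{series} rows: TRUE
#'   rows are excluded (masked out).
#' @return Named numeric vector of length 46 in \code{\link{feature_names}}
#'   order, or NULL if the event is feature-degenerate.
#' @export
aggregate_event <- function(start, end, series, mask = NULL) {
  sel <- series$center_s >= start & series$center_s < end
  if (!is.null(mask)) sel <- sel & !mask
  if (sum(sel) < 3L) return(NULL)
  sub <- series[sel, , drop = FALSE]
  n <- nrow(sub)
  out <- numeric(0)
  for (s in SCALAR_SERIES) {
    v <- sub[[s]]
    srt <- sort(v)
    out[paste0(s, "_min")] <- srt[1]
    out[paste0(s, "_low3")] <- mean(srt[1:3])
    out[paste0(s, "_p10")] <- stats::quantile(v, 0.10, names = FALSE)
    out[paste0(s, "_p25")] <- stats::quantile(v, 0.25, names = FALSE)
  }
  for (s in PEAK_SERIES) {
    v <- sub[[s]]
    out[paste0(s, "_min")] <- min(v)
    for (k in 0:2) {
      out[paste0(s, "_n", k)] <- sum(v == k)
      out[paste0(s, "_p", k)] <- sum(v == k) / n
    }
  }
  out[feature_names()]
}

#' Per-event feature matrix for a patient
#'
#' Runs \code{\link{aggregate_event}} for every event; events with too few
#' usable windows are flagged degenerate (and later rejected).
#'
#' @param events A \code{respiratory_events} table.
#' @param series A \code{window_features} data.frame.
#' @param mask Optional logical exclusion mask over series rows.
#' @return List with \code{features} (matrix, one row per event, NA rows for
#'   degenerate events) and \code{degenerate} (logical per event).
#' @export
event_feature_matrix <- function(events, series, mask = NULL) {
  nm <- feature_names()
  feats <- matrix(NA_real_, nrow = nrow(events), ncol = length(nm),
                  dimnames = list(events$event_id, nm))
  degen <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    v <- aggregate_event(events$start[i], events$end[i], series, mask)
    if (is.null(v)) degen[i] <- TRUE else feats[i, ] <- v
  }
  list(features = feats, degenerate = degen)
}
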