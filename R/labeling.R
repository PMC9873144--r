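#' Presence-consensus ground truth from two PSG scorings
#'
#' Expert annotations are retained only when some local annotation overlaps
#' them (consensus on presence, not necessarily on type), and mixed events
#' are binarized to central: a single-channel device cannot separate the
#' central onset of a mixed event from a purely central one, so the target
#' quantity is central + mixed events per hour.
#'
#' @param expert Expert-analysis \code{\link{respiratory_events}} (typed).
#' @param local Local-analysis events (types ignored; presence only).
#' @return A \code{respiratory_events} table (source \code{"expert"}) with
#'   types in \{central, obstructive\}, sorted by start.
#' @export
consensus_filter <- function(expert, local) {
  if (!nrow(expert))
    return(respiratory_events(numeric(0), numeric(0), source = "expert",
                              type = character(0)))
  keep <- vapply(seq_len(nrow(expert)), function(i) {
    any(intervals_overlap(expert$start[i], expert$end[i],
                          local$start, local$end))
  }, logical(1))
  gt <- expert[keep, , drop = FALSE]
  ty <- ifelse(gt$type == "mixed", "central", gt$type)
  respiratory_events(gt$start, gt$end, source = "expert", type = ty)
}

#' Label detected events from ground-truth annotations
#'
#' Detected (HSAT) events are processed in ascending start order. Each event
#' is matched to the unconsumed ground-truth annotations overlapping it; if
#' none overlap, to the single unconsumed annotation ending at most
#' \code{gap_s} seconds before the event starts (nearest-ending one on ties),
#' accommodating the detector's imperfect event delimitation. A matched event
#' is labeled central if any of its matches is central, otherwise
#' obstructive; each annotation is consumed at most once. Unmatched events
#' are flagged removed — from the training set only; evaluation keeps every
#' event.
#'
#' @param pat Detected events (\code{\link{respiratory_events}}).
#' @param gt Ground-truth events from \code{\link{consensus_filter}}.
#' @param gap_s Maximum allowed gap between an annotation's end and the
#'   detected event's start (default 10 s).
#' @return The \code{pat} table with added columns \code{label}
#'   (\code{"central"}, \code{"obstructive"} or NA), \code{removed}
#'   (logical: unusable for training) and \code{matched_gt} (comma-joined
#'   ids of consumed annotations).
#' @export
label_pat_events <- function(pat, gt, gap_s = 10) {
  pat <- pat[order(pat$start), , drop = FALSE]
  n <- nrow(pat)
  label <- rep(NA_character_, n)
  matched <- character(n)
  consumed <- logical(nrow(gt))
  for (i in seq_len(n)) {
    ov <- which(!consumed &
                  intervals_overlap(pat$start[i], pat$end[i], gt$start, gt$end))
    if (!length(ov)) {
      # preceding annotation ending within (start - gap_s, start]
      pre <- which(!consumed & gt$end <= pat$start[i] &
                     gt$end > pat$start[i] - gap_s)
      if (length(pre)) ov <- pre[which.max(gt$end[pre])]
    }
    if (length(ov)) {
      label[i] <- if (any(gt$type[ov] == "central")) "central" else
        "obstructive"
      consumed[ov] <- TRUE
      matched[i] <- paste(gt$event_id[ov], collapse = ",")
    }
  }
  pat$label <- label
  pat$removed <- is.na(label)
  pat$matched_gt <- matched
  pat
}
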