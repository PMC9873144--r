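#' Detect local maxima with a minimum separation
#'
#' Strict local maxima (greater than both neighbors; for flat tops, the first
#' sample of the plateau) are found, then thinned greedily by descending
#' height so that no two retained peaks are closer than \code{min_dist}
#' samples. Used both for cardiac beat detection on the filtered PPG and for
#' breathing-peak counting on the PPGDR.
#'
#' @param x Numeric signal.
#' @param min_dist Minimum separation between retained peaks, in samples.
#' @return Integer vector of peak indices (1-based), in increasing order.
#' @export
find_peaks <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # rise-then-fall; treat plateau edges via sign of nearest nonzero diff
  s <- sign(d)
  # propagate last nonzero sign forward so plateaus inherit the rising side
  nz <- s != 0
  s_f <- s
  if (any(nz)) {
    idx <- cumsum(nz)
    filled <- c(0, s[nz])[idx + 1L]
    s_f[!nz] <- filled[!nz]
  }
  cand <- which(diff(s_f) < 0) + 1L
  if (!length(cand)) return(integer(0))
  if (min_dist <= 1L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_dist)) taken <- c(taken, p)
  }
  sort(taken)
}

#' Peak prominence
#'
#' For each peak index, the height of the peak above the higher of the two
#' minima separating it from the nearest higher terrain (or signal edge) on
#' either side — the standard topographic prominence definition.
#'
#' @param x Numeric signal.
#' @param peaks Integer vector of peak indices into \code{x}.
#' @return Numeric vector of prominences, parallel to \code{peaks}.
#' @export
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left to the first sample higher than the peak (or edge)
    li <- p - 1L
    lmin <- h
    while (li >= 1L && x[li] <= h) {
      if (x[li] < lmin) lmin <- x[li]
      li <- li - 1L
    }
    ri <- p + 1L
    rmin <- h
    n <- length(x)
    while (ri <= n && x[ri] <= h) {
      if (x[ri] < rmin) rmin <- x[ri]
      ri <- ri + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}
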