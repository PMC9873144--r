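#' Read a PPG waveform from CSV or EDF
#'
#' CSV files must have columns \code{time_s, ppg} with strictly increasing
#' time; the sampling rate is the reciprocal of the median time step. EDF
#' files are read with a minimal built-in parser (EDF is a fixed-layout
#' ASCII header plus little-endian int16 records); the named channel is
#' scaled to physical units and its rate taken from the header.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"edf"}.
#' @param channel EDF channel label to extract (default \code{"PPG"}).
#' @param patient_id Identifier for the returned recording (default: file
#'   name without extension).
#' @return A \code{\link{ppg_recording}}.
#' @export
read_ppg <- function(path, format = c("auto", "csv", "edf"),
                     channel = "PPG", patient_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("time_s", "ppg") %in% names(df)))
      stop("PPG CSV must have columns time_s, ppg")
    dt <- diff(df$time_s)
    if (any(dt <= 0))
      stop("time_s must be strictly increasing (duplicated or non-monotone ",
           "timestamps)")
    fs <- 1 / stats::median(dt)
    ppg_recording(df$ppg, fs, patient_id = patient_id,
                  start_time = df$time_s[1])
  } else {
    edf <- read_edf(path)
    i <- match(channel, edf$labels)
    if (is.na(i))
      stop(sprintf("EDF has no channel '%s' (channels: %s)", channel,
                   paste(edf$labels, collapse = ", ")))
    ppg_recording(edf$signals[[i]], edf$fs[i], patient_id = patient_id)
  }
}

# Minimal EDF reader: header, signal headers, then data records of
# little-endian int16 scaled from digital to physical range.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8))
  fld(32)
  seek(con, header_bytes)
  sig <- lapply(seq_len(ns), function(i) numeric(n_records * nsamp[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
      phys <- (d - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) +
        pmin_[i]
      sig[[i]][((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
    }
  }
  list(labels = labels, signals = sig, fs = nsamp / record_dur,
       record_dur = record_dur, n_records = n_records)
}

# EDF writer used only to build binary test fixtures at run time (the
# package itself writes CSV/JSON only).
write_edf <- function(path, signals, fs, labels, record_dur = 1) {
  ns <- length(signals)
  stopifnot(length(fs) == ns, length(labels) == ns)
  nsamp <- as.integer(round(fs * record_dur))
  n_records <- min(vapply(seq_len(ns),
                          function(i) length(signals[[i]]) %/% nsamp[i],
                          numeric(1)))
  pmin_ <- vapply(signals, min, numeric(1))
  pmax_ <- vapply(signals, max, numeric(1))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(formatC(substr(x, 1, w), width = -w), con,
                                 nchars = w, eos = NULL)
  header_bytes <- 256 + ns * 256
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(format(header_bytes), 8); wr("", 44)
  wr(format(n_records), 8); wr(format(record_dur), 8); wr(format(ns), 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("au", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i]), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(format(nsamp[i]), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][((r - 1) * nsamp[i] + 1):(r * nsamp[i])]
      dig <- round((seg - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a respiratory-event table from CSV
#'
#' Expected columns: \code{start_s, end_s, source, type} (type may be
#' empty for unlabeled events). Events are returned sorted by start.
#'
#' @param path CSV file path.
#' @return A \code{\link{respiratory_events}} table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(type = "character"))
  need <- c("start_s", "end_s", "source", "type")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns ", paste(need, collapse = ", "))
  if (any(df$end_s <= df$start_s))
    stop("event end_s must exceed start_s")
  ty <- ifelse(is.na(df$type) | df$type == "", "unlabeled", df$type)
  respiratory_events(df$start_s, df$end_s, source = df$source, type = ty)
}

#' Write a respiratory-event table to CSV
#'
#' @param events A \code{\link{respiratory_events}} table.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(start_s = events$start, end_s = events$end,
                   source = events$source,
                   type = ifelse(events$type == "unlabeled", "", events$type))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a cohort evaluation report to JSON
#'
#' Versioned JSON containing the per-patient predictions (cAHI, ERP,
#' rejection counts) and, per cutoff, the screening metric block
#' (sensitivity/specificity/ppv/npv/kappa and friends). An empty cohort
#' yields zero patients and null metrics.
#'
#' @param evaluation A \code{cohort_evaluation}, or NULL for an empty report.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_report <- function(evaluation, path) {
  if (is.null(evaluation)) {
    obj <- list(schema_version = REPORT_SCHEMA_VERSION, n_patients = 0L,
                patients = list(), metrics = NULL)
  } else {
    metr <- lapply(evaluation$metrics, function(m)
      list(cutoff = m$cutoff,
           sensitivity = m$sensitivity, sensitivity_ci = m$sensitivity_ci,
           specificity = m$specificity, specificity_ci = m$specificity_ci,
           ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
           lr_plus = m$lr_plus, lr_minus = m$lr_minus,
           kappa = m$kappa, kappa_ci = m$kappa_ci))
    obj <- list(schema_version = REPORT_SCHEMA_VERSION,
                n_patients = nrow(evaluation$patients),
                patients = evaluation$patients,
                metrics = metr,
                pearson = evaluation$pearson,
                confusion = list(
                  table = unclass(evaluation$confusion$table),
                  labels = CAHI_BIN_LABELS,
                  accuracy = evaluation$confusion$accuracy,
                  kappa = evaluation$confusion$kappa),
                sweep = evaluation$sweep)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Report path written by \code{\link{write_report}}.
#' @return Parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
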