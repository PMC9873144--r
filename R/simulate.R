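#' Specify a synthetic PPG recording
#'
#' Describes one simulated finger-PPG recording: a cardiac pulse train whose
#' pulse amplitude is modulated by breathing, with optional respiratory
#' events, vasoconstriction amplitude collapses and irregular-beat zones.
#' Central (and mixed) events suppress the amplitude modulation down to
#' \code{residual_mod}; obstructive events retain it (effort continues
#' against the obstructed airway).
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param heart_rate_bpm Mean heart rate (beats per minute).
#' @param hr_jitter_frac SD of multiplicative beat-to-beat interval jitter.
#' @param resp_freq_hz Breathing frequency in Hz (adult range 0.2-0.33).
#' @param resp_mod_depth Fractional amplitude modulation depth m in [0,1]:
#'   pulse amplitude swings between (1-m) and (1+m) of its baseline.
#' @param events data.frame with columns \code{start, end, type} and optional
#'   \code{residual_mod} (default 0): ground-truth respiratory events.
#' @param vaso_zones data.frame with columns \code{start, end, attenuation}:
#'   intervals where all pulse amplitudes are scaled by \code{attenuation}.
#' @param arrhythmia_zones data.frame with columns \code{start, end,
#'   interval_jitter_frac}: intervals where beat intervals are multiplied by
#'   (1 + U(-j, +j)).
#' @param noise_sd SD of additive white noise (pulse amplitude is ~1).
#' @param rng_seed Integer seed.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(duration_s = 600, fs = 25,
                            heart_rate_bpm = 65, hr_jitter_frac = 0.03,
                            resp_freq_hz = 0.25, resp_mod_depth = 0.3,
                            events = NULL, vaso_zones = NULL,
                            arrhythmia_zones = NULL,
                            noise_sd = 0, rng_seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, heart_rate_bpm > 0,
            resp_freq_hz > 0, resp_mod_depth >= 0, resp_mod_depth <= 1,
            noise_sd >= 0)
  if (is.null(events)) {
    events <- data.frame(start = numeric(0), end = numeric(0),
                         type = character(0), residual_mod = numeric(0))
  } else {
    if (is.null(events$residual_mod)) events$residual_mod <- 0
    if (any(events$end <= events$start)) stop("event end must exceed start")
    if (any(events$start < 0) || any(events$end > duration_s))
      stop("events must lie within the recording duration")
    if (!all(events$type %in% c("central", "obstructive", "mixed")))
      stop("event type must be central, obstructive or mixed")
    if (any(events$residual_mod < 0 | events$residual_mod > 1))
      stop("residual_mod must lie in [0,1]")
    central_like <- events$type %in% c("central", "mixed")
    if (any(central_like & events$residual_mod > resp_mod_depth))
      stop("central events cannot have residual_mod above resp_mod_depth")
    ev <- events[order(events$start), , drop = FALSE]
    if (nrow(ev) > 1L) {
      ov <- which(ev$start[-1L] < ev$end[-nrow(ev)])
      if (length(ov) && any(ev$type[ov] != ev$type[ov + 1L]))
        stop("overlapping events of different types are not allowed")
    }
    events <- ev
  }
  for (zn in list(vaso_zones, arrhythmia_zones)) {
    if (!is.null(zn) && nrow(zn) &&
        (any(zn$start < 0) || any(zn$end > duration_s)))
      stop("zones must lie within the recording duration")
  }
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_frac = hr_jitter_frac,
                 resp_freq_hz = resp_freq_hz,
                 resp_mod_depth = resp_mod_depth,
                 events = events, vaso_zones = vaso_zones,
                 arrhythmia_zones = arrhythmia_zones,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

# asymmetric pulse: fast systolic rise, slow diastolic decay
pulse_template <- function(fs) {
  tau <- seq(0, 0.6, by = 1 / fs)
  t0 <- 0.12
  sig <- ifelse(tau < t0, 0.045, 0.13)
  exp(-(tau - t0)^2 / (2 * sig^2))
}

in_interval <- function(t, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(tab))) out <- out | (t >= tab$start[i] & t < tab$end[i])
  out
}

#' Simulate a PPG recording with ground-truth events
#'
#' Generates \code{PPG(t) = sum_beats A_beat * pulse(t - t_beat) + noise}
#' where \code{A_beat = 1 + m_eff * sin(2 pi f_resp t_beat)}. The effective
#' depth \code{m_eff} is the spec's \code{resp_mod_depth} outside events and
#' inside obstructive events, and the event's \code{residual_mod} inside
#' central/mixed events. Vasoconstriction zones scale all amplitudes by their
#' attenuation (with a 2 s cosine taper at the edges); arrhythmia zones
#' perturb beat intervals multiplicatively.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return List with \code{recording} (a \code{\link{ppg_recording}}) and
#'   \code{events} (ground-truth \code{\link{respiratory_events}} with types).
#' @export
simulate_ppg <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  n <- floor(spec$duration_s * spec$fs)
  base_int <- 60 / spec$heart_rate_bpm
  # draw beats past the end so the last pulses are complete
  n_beats <- ceiling(spec$duration_s / base_int * 1.5) + 5L
  ints <- base_int * (1 + stats::rnorm(n_beats, 0, spec$hr_jitter_frac))
  ints <- pmax(ints, 0.3)
  t_beats <- cumsum(c(stats::runif(1, 0, base_int), ints))
  if (!is.null(spec$arrhythmia_zones) && nrow(spec$arrhythmia_zones)) {
    # rebuild the train, stretching intervals whose onset lies in a zone
    t <- t_beats[1]
    out <- t
    for (i in seq_along(ints)) {
      d <- ints[i]
      for (k in seq_len(nrow(spec$arrhythmia_zones))) {
        z <- spec$arrhythmia_zones[k, ]
        if (t >= z$start && t < z$end)
          d <- d * (1 + stats::runif(1, -z$interval_jitter_frac,
                                     z$interval_jitter_frac))
      }
      t <- t + d
      out <- c(out, t)
    }
    t_beats <- out
  }
  t_beats <- t_beats[t_beats < spec$duration_s]

  ev <- spec$events
  central_tab <- ev[ev$type %in% c("central", "mixed"), , drop = FALSE]
  obstr_tab <- ev[ev$type == "obstructive", , drop = FALSE]
  m_eff <- rep(spec$resp_mod_depth, length(t_beats))
  if (nrow(central_tab)) {
    for (i in seq_len(nrow(central_tab))) {
      inside <- t_beats >= central_tab$start[i] & t_beats < central_tab$end[i]
      m_eff[inside] <- central_tab$residual_mod[i]
    }
  }
  # obstructive events keep modulation depth m (effort persists)
  if (nrow(obstr_tab)) invisible(NULL)

  amp <- 1 + m_eff * sin(2 * pi * spec$resp_freq_hz * t_beats)
  if (!is.null(spec$vaso_zones) && nrow(spec$vaso_zones)) {
    taper <- 2 # seconds of cosine ramp at each zone edge
    for (k in seq_len(nrow(spec$vaso_zones))) {
      z <- spec$vaso_zones[k, ]
      w <- rep(1, length(t_beats))
      core <- t_beats >= z$start & t_beats < z$end
      w[core] <- z$attenuation
      ramp_in <- t_beats >= z$start - taper & t_beats < z$start
      w[ramp_in] <- 1 - (1 - z$attenuation) *
        (1 + cos(pi * (z$start - t_beats[ramp_in]) / taper)) / 2
      ramp_out <- t_beats >= z$end & t_beats < z$end + taper
      w[ramp_out] <- 1 - (1 - z$attenuation) *
        (1 + cos(pi * (t_beats[ramp_out] - z$end) / taper)) / 2
      amp <- amp * w
    }
  }

  tpl <- pulse_template(spec$fs)
  x <- numeric(n + length(tpl))
  idx0 <- floor(t_beats * spec$fs) + 1L
  for (b in seq_along(t_beats)) {
    i <- idx0[b]
    x[i:(i + length(tpl) - 1L)] <- x[i:(i + length(tpl) - 1L)] + amp[b] * tpl
  }
  x <- x[seq_len(n)]
  tt <- (seq_len(n) - 1L) / spec$fs
  x <- x + 0.4 * sin(2 * pi * 0.03 * tt) # slow vasomotor baseline drift
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)

  rec <- ppg_recording(x, spec$fs, patient_id = "sim")
  gt <- if (nrow(ev)) {
    respiratory_events(ev$start, ev$end, source = "expert", type = ev$type)
  } else {
    respiratory_events(numeric(0), numeric(0), source = "expert",
                       type = character(0))
  }
  list(recording = rec, events = gt)
}

#' Envelope-measured respiratory modulation depth
#'
#' Measures the fractional amplitude modulation of a PPG recording from its
#' pulse amplitudes: beats are detected on the high-pass-filtered signal and
#' each beat's peak-to-trough amplitude (peak minus the minimum over the
#' preceding 0.3 s) is taken, which cancels baseline and pulse-train-mean
#' offsets. The depth is \code{(q97.5 - q2.5) / (q97.5 + q2.5)} of the
#' per-beat amplitude series; for pulse amplitudes swinging sinusoidally
#' between (1-m) and (1+m) this estimates m.
#'
#' @param ppg A \code{ppg_recording}.
#' @param config A \code{\link{pipeline_config}}.
#' @param trim_s Seconds discarded at each edge before measuring.
#' @return Estimated modulation depth (scalar).
#' @export
ppg_modulation_depth <- function(ppg, config = pipeline_config(), trim_s = 10) {
  filt <- highpass(ppg, config$hp_cutoff_hz)
  fs <- ppg$fs
  pk <- find_peaks(filt, max(1L, round(config$min_peak_dist_ms / 1000 * fs)))
  tpk <- (pk - 1) / fs
  dur <- recording_duration(ppg)
  pk <- pk[tpk >= trim_s & tpk <= dur - trim_s]
  back <- round(0.3 * fs)
  amp <- vapply(pk, function(i)
    filt[i] - min(filt[max(1L, i - back):i]), numeric(1))
  amp <- amp[amp > 0.25 * stats::median(amp)] # drop non-beat ripples
  q <- stats::quantile(amp, c(0.025, 0.975), names = FALSE)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Specify a synthetic patient cohort
#'
#' Stands in for a clinical HSAT cohort: each patient gets a simulated
#' overnight-like recording (scaled down in duration), ground-truth events,
#' and three derived event lists — the HSAT detector output (timing jitter,
#' no types), an expert PSG scoring (types, optional label noise) and a local
#' PSG scoring (presence only, optional misses) — so the labeling,
#' consensus-filtering and LOOCV stages are all exercised.
#'
#' @param n_patients Number of patients.
#' @param csa_prevalence Probability a patient is a CSA case (high central
#'   event fraction).
#' @param duration_s Recording duration per patient in seconds.
#' @param fs Sampling rate in Hz.
#' @param separation Class-separation regime: \code{"strong"} (deep, clean
#'   modulation; near-zero residual effort in central events) or
#'   \code{"moderate"} (shallower modulation, residual effort, more noise).
#' @param timing_jitter_s SD (s) of the timing jitter applied to the HSAT
#'   detector's event boundaries.
#' @param label_noise Probability an expert label is flipped.
#' @param local_miss_prob Probability the local scoring misses an event.
#' @param rng_seed Integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 30, csa_prevalence = 0.3,
                        duration_s = 900, fs = 25,
                        separation = c("strong", "moderate"),
                        timing_jitter_s = 1, label_noise = 0.02,
                        local_miss_prob = 0.05, rng_seed = 1L) {
  separation <- match.arg(separation)
  stopifnot(n_patients >= 1, csa_prevalence >= 0, csa_prevalence <= 1,
            duration_s > 0, timing_jitter_s >= 0,
            label_noise >= 0, label_noise <= 1,
            local_miss_prob >= 0, local_miss_prob <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 csa_prevalence = csa_prevalence, duration_s = duration_s,
                 fs = fs, separation = separation,
                 timing_jitter_s = timing_jitter_s, label_noise = label_noise,
                 local_miss_prob = local_miss_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

jitter_events <- function(ev, sd_s, duration_s) {
  if (!nrow(ev) || sd_s <= 0) return(ev)
  s <- ev$start + stats::rnorm(nrow(ev), 0, sd_s)
  e <- ev$end + stats::rnorm(nrow(ev), 0, sd_s)
  e <- pmax(e, s + 5) # keep a sensible minimum duration
  s <- pmax(s, 0)
  e <- pmin(e, duration_s)
  ev$start <- s
  ev$end <- e
  ev[order(ev$start), , drop = FALSE]
}

#' Simulate a patient cohort
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List of \code{\link{patient_record}} objects. Each carries the
#'   generator's own true cAHI ((central + mixed events) / TST hours) for
#'   parameter-recovery checks.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  sep <- spec$separation
  patients <- vector("list", spec$n_patients)
  seeds <- sample.int(.Machine$integer.max, spec$n_patients)
  is_csa <- stats::runif(spec$n_patients) < spec$csa_prevalence
  for (p in seq_len(spec$n_patients)) {
    hr <- stats::runif(1, 55, 75)
    f_resp <- stats::runif(1, 0.2, 0.33)
    m <- if (sep == "strong") stats::runif(1, 0.3, 0.45) else
      stats::runif(1, 0.15, 0.3)
    resid_hi <- if (sep == "strong") 0.03 else 0.12
    noise_sd <- if (sep == "strong") 0.01 else 0.05
    central_frac <- if (is_csa[p]) stats::runif(1, 0.55, 0.9) else
      stats::runif(1, 0, 0.1)
    # alternate gap/event; leave 60 s of clean signal at each end
    # apnea-like durations: >= 10 s but well under the 30 s normalization
    # window, as in clinical scorings
    evs <- list()
    t <- 60 + stats::runif(1, 0, 20)
    while (TRUE) {
      d <- stats::runif(1, 12, 22)
      if (t + d > spec$duration_s - 60) break
      ty <- if (stats::runif(1) < central_frac) {
        if (stats::runif(1) < 0.15) "mixed" else "central"
      } else "obstructive"
      rm <- if (ty == "obstructive") 0 else stats::runif(1, 0, resid_hi)
      evs[[length(evs) + 1L]] <- data.frame(start = t, end = t + d, type = ty,
                                            residual_mod = rm)
      t <- t + d + stats::runif(1, 25, 55)
    }
    evtab <- do.call(rbind, evs)
    sim <- simulate_ppg(simulation_spec(
      duration_s = spec$duration_s, fs = spec$fs, heart_rate_bpm = hr,
      resp_freq_hz = f_resp, resp_mod_depth = m, events = evtab,
      noise_sd = noise_sd, rng_seed = seeds[p]))
    sim$recording$patient_id <- sprintf("sim%03d", p)
    gt <- sim$events
    tst_hours <- spec$duration_s / 3600
    true_cahi <- sum(gt$type %in% c("central", "mixed")) / tst_hours

    pat <- jitter_events(gt, spec$timing_jitter_s, spec$duration_s)
    pat <- respiratory_events(pat$start, pat$end, source = "pat_hsat",
                              type = "unlabeled")
    expert <- gt
    if (spec$label_noise > 0 && nrow(expert)) {
      flip <- stats::runif(nrow(expert)) < spec$label_noise
      expert$type[flip] <- ifelse(
        expert$type[flip] %in% c("central", "mixed"), "obstructive", "central")
    }
    expert <- respiratory_events(expert$start, expert$end, source = "expert",
                                 type = expert$type)
    keep_local <- stats::runif(nrow(gt)) >= spec$local_miss_prob
    local <- jitter_events(gt[keep_local, , drop = FALSE], 0.5,
                           spec$duration_s)
    local <- respiratory_events(local$start, local$end, source = "local",
                                type = local$type)
    patients[[p]] <- patient_record(sim$recording, pat, tst_hours,
                                    expert_events = expert,
                                    local_events = local,
                                    true_cahi = true_cahi)
  }
  patients
}
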