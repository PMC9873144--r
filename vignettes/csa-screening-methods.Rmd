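---
title: "Detecting central sleep apnea from finger PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting central sleep apnea from finger PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgcsa)
```

## The problem

Obstructive and central sleep apnea (OSA, CSA) both interrupt airflow during
sleep, but for different reasons: in OSA the upper airway collapses while
breathing effort continues; in CSA the neural drive to breathe is absent, so
effort itself stops. The distinction matters clinically — the therapies
differ — but home sleep apnea tests built around a single finger
photoplethysmography (PPG) probe have no airflow or effort-belt channel to
make it.

`ppgcsa` implements a screening pipeline that makes the distinction from the
finger PPG alone. The physiological lever is that intrathoracic pressure
swings modulate peripheral blood volume: the PPG pulse amplitude oscillates
in synchrony with breathing at the adult respiratory rate (0.2–0.33 Hz).
When breathing effort ceases, that amplitude modulation vanishes; when
effort continues against an obstructed airway, it persists. Demodulating the
pulse-amplitude envelope therefore yields a surrogate respiratory-effort
signal — here called the PPG-derived respiratory effort, PPGDR — that is
locally flat during central events and keeps oscillating during obstructive
ones.

The pipeline takes as inputs a raw PPG waveform, a list of detected
respiratory events (produced upstream by the home-test's event detector;
event detection is out of scope here), and a total sleep time (TST)
estimate. It outputs a per-patient central apnea–hypopnea index (cAHI,
central + mixed events per hour of sleep) and screening decisions at cAHI
cutoffs of 5, 10 and 15 events/h.

## Respiratory effort extraction

Three steps turn raw PPG into the PPGDR:

1. **High-pass filter, 0.15 Hz.** Removes baseline drift and vasomotor
   wander below the breathing band. Realized as a 4th-order Butterworth
   applied forward–backward for zero phase, so event timing is not shifted.
   The forward–backward pass is preceded by odd-reflection padding of about
   three cutoff periods at each end; without it, IIR edge transients at this
   low a normalized cutoff would contaminate tens of seconds of signal.
2. **Peak envelope.** Pulse-wise local maxima (minimum separation 250 ms)
   are interpolated with a monotone (Fritsch–Carlson) cubic spline and
   resampled at the signal rate. Monotone interpolation avoids the
   overshoot a plain cubic spline adds between beats of unequal amplitude.
   Candidate maxima whose topographic prominence falls below 10% of the
   90th-percentile prominence are discarded: they are between-beat ripple,
   not pulses, and would drag the envelope to the inter-beat baseline.
3. **Normalization.** A 6-s centered moving average is subtracted (residual
   baseline) and the result divided by a 30-s centered moving interquartile
   range (steady-state amplitude changes, e.g. perfusion level or probe
   coupling). Windows shrink at the recording edges. The IQR divisor is
   floored at `1e-6 × median(|envelope|)` (and at `1e-12` absolutely) so a
   flatlined envelope yields 0, never NaN or Inf.

The IQR window being 30 s has a consequence worth stating: the flat-zone
contrast that the classifier relies on exists because respiratory events
(10–25 s) are shorter than the normalization window, so the window always
spans some modulated surroundings. An event much longer than 30 s would be
renormalized against its own flatness. Clinical event durations satisfy
this comfortably; the simulator draws durations from 12–22 s for the same
reason.

## Features

Windows of 5, 7, 11 and 21 s slide over the PPGDR with a 1-s stride; each
window's features are ascribed to the one-second interval at its center.
Per window: the range for all four lengths, plus the interquartile range,
population variance and breathing-peak count (local maxima, minimum
separation 250 ms) for the 11-s and 21-s lengths. A flat, effort-less
PPGDR gives near-zero dispersion and few or no peaks.

Per respiratory event, the window rows whose center-second falls inside the
event (half-open `[start, end)`) are aggregated: minimum, mean of the three
lowest values, and 10th/25th percentiles for the eight dispersion series;
minimum plus counts and proportions of windows with zero, one and two peaks
for the two peak-count series. That yields a frozen, versioned 46-value
vector per event. Aggregating minima and low percentiles makes the features
robust to the variable position and duration of the flat zone within the
detected event. Fewer than three usable windows cannot support the
lowest-three mean; such events are flagged degenerate and count as rejected.

Percentiles use linear interpolation between order statistics and variance
is the population form — both conventions are arbitrary but frozen, since
the classifier contract depends on them.

## Quality rejection

Three layers, in order:

* **Signal**: strong vasoconstrictions collapse pulse amplitude and leave
  low-SNR episodes that normalization amplifies rather than rescues. The
  pulse-amplitude trend (peak envelope low-passed at 0.05 Hz, removing both
  pulse and breathing content) is searched for troughs of prominence above
  50% of a 120-s rolling-median baseline; each trough is expanded to the
  region where the trend stays below 70% of baseline. Feature windows
  centered inside such zones are excluded from event aggregation. The
  prominence and recovery fractions are not physiological constants; they
  are exposed in `pipeline_config()` and documented as tunable.
* **Event**: peak-to-peak intervals of the PPG are flagged irregular when
  two neighbors differ by more than 20% of their mean (either neighboring
  pair suffices for the shared interval). An event with strictly more than
  20% irregular intervals — intervals assigned by their midpoints, under
  the half-open convention — is rejected, as is an event containing no
  beats at all. The per-patient fraction of rejected events is the event
  rejection proportion (ERP).
* **Patient**: ERP strictly above 0.3 rejects the patient; too few retained
  events make the extrapolated cAHI unreliable. Both the 20% and 0.3
  thresholds are strict inequalities.

## Labeling, classification and cAHI

For training, ground truth comes from two independent PSG scorings: expert
annotations corroborated by the local scoring (consensus on presence, not
type) survive, with mixed events binarized to central — a single-channel
device cannot separate a mixed event's central onset from a pure central
event, so the target is central + mixed events per hour. Detected events
are then matched greedily in ascending start order: overlapping unconsumed
annotations first; failing that, the nearest unconsumed annotation ending
at most 10 s before the event start (the detector delimits events
imperfectly, so a small systematic lag is tolerated). A matched event is
central if any match is central; each annotation is consumed at most once;
unmatched events are excluded from training only — evaluation keeps every
non-rejected event.

The classifier is a bagged ensemble of 30 CART trees (bootstrap resamples
of the training events, each tree pruned to at most 150 internal splits).
The score of an event is the fraction of trees voting central. The
false-positive cost of 2.5 — the cost of calling an obstructive event
central — enters as a decision-threshold shift: call central only when the
score strictly exceeds `2.5/3.5 ≈ 0.714`, ties going to obstructive. The
threshold realization was chosen over per-tree loss matrices because it
makes the conservative bias explicit and the predicted-central count
exactly non-increasing in the cost. Over-calling CSA is the failure mode a
screen must avoid: flagged patients are referred to in-lab PSG.

Evaluation is a patient-wise leave-one-out cross-validation: for each
retained patient, the ensemble is trained on all other retained patients'
labeled non-rejected events and applied to the held-out patient's
non-rejected events. The predicted cAHI is the predicted-central count over
TST, extrapolated by `1/(1 − ERP)` to account for the rejected share. Fold
bookkeeping (training and held-out event ids) is retained so leakage can be
audited mechanically.

Feature importance follows the split-risk convention: each branch node's
risk decrease is credited to its splitting feature and the per-feature sums
are divided by the ensemble's total branch-node count.

## Screening evaluation

Per cutoff (5, 10, 15 events/h): sensitivity, specificity, LR+, LR−, PPV,
NPV, accuracy and Cohen's kappa, with Wilson score intervals for the
proportions and a seeded 2000-replicate bootstrap interval for kappa (the
interval methods are conventional choices, frozen here). Patients are
flagged at `cAHI ≥ cutoff` — a patient sitting exactly on the cutoff is
flagged, matching clinical usage. ROC and PR curves vary the event-score
threshold only (no refitting), recomputing each patient's cAHI and flag at
every distinct score; AUCs are trapezoidal. A 4-class confusion matrix over
cAHI bins {<5, [5,10), [10,15), ≥15} with multiclass accuracy and
unweighted kappa, Pearson correlation with a least-squares line, and a
PPV/NPV sweep over cutoffs 0–15 (step 0.5, reporting the argmax of
PPV + NPV) complete the picture.

## The synthetic cohort

No clinical recordings ship with the package; every downstream stage is
validated against a simulator with known ground truth. A recording is a
train of asymmetric pulses (fast systolic rise, slow decay) at a jittered
heart rate, whose per-beat amplitude is `1 + m·sin(2π f_resp t)` with
depth `m` and breathing rate `f_resp ∈ [0.2, 0.33]` Hz. Central (and
mixed) events suppress the depth to a small residual; obstructive events
retain it; vasoconstriction zones scale all amplitudes by an attenuation
factor with 2-s cosine tapers; arrhythmia zones multiply beat intervals by
`1 + U(−j, j)`. Slow vasomotor drift and white noise are added on top.

The cohort generator draws per-patient physiology and an alternating
gap/event schedule (events 12–22 s, gaps 25–55 s), assigns each patient a
central-event fraction — high (0.55–0.9) for CSA cases, low (0–0.1)
otherwise, with the CSA prevalence configurable — and derives three event
lists from the ground truth: the detector's (timing jitter, no types), an
expert scoring (types, small label-noise option) and a local scoring
(presence only, occasional misses), so the consensus and matching rules
are actually exercised. Under the default "strong" separation regime the
modulation is deep (0.3–0.45), the central residual near zero and the
noise low; a "moderate" regime exists for stress testing.

The study size used throughout the tests and the acceptance script is 30
patients × 900-s recordings at 25 Hz with TST set to the recording
duration — a deliberately scaled-down stand-in for an overnight clinical
cohort, sized so a full LOOCV runs in well under a minute while still
spanning all four cAHI categories. Event densities are scaled accordingly,
so per-patient cAHI values span the clinical cutoffs.

What the simulator does **not** model: real PPG morphology (dicrotic
notches, probe-specific waveforms), SpO2 and pulse-rate dynamics,
post-event sympathetic amplitude dips, sleep-stage structure, or the messy
co-occurrence of artifact and pathology. Passing tests on this cohort
demonstrate that the pipeline recovers the information the signal model
encodes — flat-effort zones — through every processing stage; they do not
certify clinical performance, which requires patient data.

## Numerical and degenerate-input policy

* Zero-phase filtering uses odd-reflection padding; constants filter to
  ~0 rather than to edge transients.
* Rolling quantiles are exact (sliding sorted window, compiled), with
  shrinking windows at the edges; quantiles are linearly interpolated.
* The envelope is held constant beyond the first/last detected pulse.
* `peak_envelope` requires at least two pulses, `irregular_intervals` at
  least two intervals, `normalize_envelope` a signal at least one IQR
  window long, `loocv` at least three retained patients — all are explicit
  errors, not silent NAs.
* ERP = 1 makes the extrapolation undefined; `compute_cahi` refuses it
  (such a patient is rejected before that point).
* Undefined metrics (empty denominators, constant score vectors) are
  returned as NA with a warning, never fabricated.
* All stochastic steps — simulation, bootstrap resampling in bagging and
  in confidence intervals — take explicit integer seeds; identical seeds
  give bit-identical results.

## Known limitations

* The vasoconstriction thresholds (prominence 0.5, recovery 0.7 of
  baseline) are heuristic; on real data they would need tuning against
  scored artifact.
* The event detector is not part of the package: event lists are inputs,
  and detector quality bounds everything downstream.
* cAHI extrapolation assumes rejected events have the same central
  fraction as retained ones.
* With a 25 Hz default sampling rate, beat-interval irregularity is
  quantized at 40 ms; at 20% of a ~1-s interval the rule has headroom, but
  much lower sampling rates would erode it.
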