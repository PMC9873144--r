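Package: ppgcsa
Title: Central Sleep Apnea Screening from Finger Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects central sleep apnea from a single finger
    photoplethysmography (PPG) channel. Extracts a PPG-derived respiratory
    effort surrogate (PPGDR) by high-pass filtering, peak-envelope
    demodulation and moving-window normalization; computes flat-effort
    features over detected respiratory events; rejects low-quality signal
    segments, events and patients; classifies events as central or
    obstructive with a cost-sensitive bagged-trees model under
    leave-one-patient-out cross-validation; and estimates a per-patient
    central apnea-hypopnea index (cAHI) with screening-test evaluation at
    clinical cutoffs. Includes a synthetic PPG cohort simulator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    rpart,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
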