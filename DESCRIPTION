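Package: rsvp300
Title: Predicting P300 Speller Performance from RSVP Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking rapid serial visual
    presentation (RSVP) behavioral and event-related potential (ERP)
    features to matrix P300 speller performance. Generates synthetic
    multichannel EEG cohorts with known ground-truth P300 parameters,
    preprocesses continuous recordings (common average reference,
    zero-phase Butterworth band-pass, epoching, artifact rejection),
    extracts per-subject RSVP features (T1 detection rate, P300 amplitude
    and latency, and their trial-level variations), scores single-trial
    speller classification with stepwise linear discriminant analysis
    (SWLDA) under cross-validated AUC, and evaluates single- and
    multi-feature regression predictors of speller performance with
    leave-one-subject-out cross-validation, group contrasts, channel-wise
    correlation topographies with FDR control, and a trial-count sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
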