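Package: preictal
Title: Seizure Forecasting from Long-Duration Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasts epileptic seizures from chronic multichannel
    intracranial EEG recordings. Implements an 11-band FIR filter bank and
    inter-electrode correlation features binned at one-minute resolution,
    power-in-band comparison features, preictal/interictal epoch labeling
    with lead-seizure identification and gap handling, class-weighted linear
    support-vector classification, overlapping-window seizure-warning
    generation, blocked five-fold cross-validation, and statistical
    evaluation (sensitivity, time in warning, false positives per day, days
    without warning, ROC/AUC) against a time-matched Poisson chance
    predictor. Includes a synthetic-data module that generates recordings
    and feature matrices with known preictal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
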