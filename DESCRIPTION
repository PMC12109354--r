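Package: dtw100
Title: Percentage Scoring of Cortico-Muscular Coupling by Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies functional cortico-muscular coupling from paired local
    field potential (LFP) and electromyography (EMG) recordings. Implements a
    complete evaluation pipeline: zero-phase preprocessing (50 Hz notch,
    moving-average baseline removal, modality-specific Butterworth bandpass),
    epoch extraction and trial averaging, construction of a healthy-reference
    signal pair, classic dynamic time warping with length normalization, and
    conversion of warping distances into bounded percentage (DTW-100) scores in
    both the time and frequency domains. Includes a deterministic synthetic
    cohort generator emulating normal, globally ischemic (BCAO), and
    ultrasound-stimulated regimes, and paired pre/post group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
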