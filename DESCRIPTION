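Package: scpdecode
Title: Single-Trial Decoding of Reaching Direction from Pre-Movement EEG
    Slow Cortical Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes the direction of self-paced center-out arm reaches from
    multichannel EEG recorded before movement onset. Implements the full
    single-trial pipeline: common average referencing, zero-phase Butterworth
    filtering and resampling, narrow-band amplitude, Hilbert-envelope and
    instantaneous-phase feature signals, 250 ms sliding-window feature
    extraction, canonical variate analysis (CVA) channel selection, four-class
    linear discriminant analysis with pooled covariance, chronological 5-fold
    cross-validation, permutation-based chance level, Wilcoxon early-detection
    analysis, and sensitivity/specificity evaluation of the selected
    classifier. Includes a synthetic-data generator that emulates the
    self-paced center-out protocol (direction-specific slow cortical
    potentials on a 1/f background) so the pipeline can be exercised and
    validated end to end, plus readers for EDF/BDF recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
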