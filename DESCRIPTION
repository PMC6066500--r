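Package: fpcoh
Title: Frontoparietal EEG Coherence and Visuomotor Tracking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for linking resting-state EEG frontoparietal coherence to
    training-related gains in visuomotor pursuit tracking. Implements an EEG
    preprocessing chain (average re-reference, zero-phase low-pass filtering,
    1-s epoching with detrending, amplitude-based epoch rejection, Infomax
    independent component analysis with automatic artifact-component flagging),
    epoch-averaged magnitude-squared coherence between electrode regions of
    interest, pursuit-tracking performance scoring (success rate and error
    rate), sigmoidal speed calibration, lesion-mask overlap arithmetic, and a
    nonparametric statistical layer (exact Spearman and Wilcoxon signed-rank
    tests) for brain-behavior prediction. A synthetic-cohort generator with
    closed-form ground-truth coherence makes every stage verifiable without
    real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
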