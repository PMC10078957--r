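Package: serpbci
Title: Electrotactile Somatosensory ERP Brain-Computer Interface Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding pipeline for an electrotactile brain-computer interface
    driven by somatosensory event-related potentials (sERP). Covers stimulus
    schedule generation and validation for a two-site forearm stimulation
    protocol, a synthetic EEG generator with schedule-locked SEP responses and
    a controllable tactile-attention effect, bandpass filtering, epoching,
    baseline correction and amplitude-threshold artifact rejection,
    consecutive-trial sERP averaging with cluster balancing and downsampling,
    difference-wave computation, amplitude-threshold feature selection,
    SVM/LDA classification under leakage-free leave-one-out cross-validation,
    repeated-measures comparison statistics, and information transfer rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    MASS,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
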