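Package: semgid
Title: Multi-Session Surface EMG Biometric Identification and Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for personal identification from two-channel surface
    electromyography (sEMG) recorded over multiple sessions. Provides a
    canonical data model and plain-text readers/writers for repetition-level
    sEMG recordings, a synthetic multi-session sEMG generator with
    quality-control rejection rules, a Butterworth bandpass plus mains-notch
    preprocessing chain with windowing and normalization, a residual 1D
    convolutional network (built and trained natively in R) that maps signal
    windows to subject-class probabilities and embeddings, an evaluation suite
    with confusion matrices and per-class/macro/weighted metrics, and an
    enrollment/verification layer with cosine-similarity templates,
    equal-error-rate threshold calibration, and credential-plus-biometric
    access modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    digest,
    openssl
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
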