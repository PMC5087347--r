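Package: eegsel
Title: ReliefF-Based EEG Sensor-Channel Selection for Emotion Recognition
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Channel (sensor) selection for multi-channel EEG emotion
    recognition. Extracts band-power features (theta, alpha, beta, gamma)
    from trial-structured recordings, scores features by multi-class
    ReliefF or by the F-score filter, aggregates feature weights into
    channel weights (MRCS: mean ReliefF channel selection), refines the
    channel ranking with a classifier-in-the-loop adjustment that
    multiplies each channel's weight by one plus its relative contribution
    to the cross-validated accuracy curve (X-MRCS), and aggregates
    rankings across subjects for subject-independent selection. Includes a
    synthetic trial generator emulating the layout of preprocessed
    affective-EEG recordings (32 channels, 128 Hz, 60-s trials, 1-9
    valence/arousal ratings) with class-discriminative band-power effects
    planted in known channels, a repeated stratified cross-validation
    harness with paired comparisons, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    Rcpp,
    signal,
    stats,
    tools,
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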