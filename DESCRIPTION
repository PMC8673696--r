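Package: mmglam
Title: Magnetomyography Analysis of Pelvic Floor Muscle Contractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing magnetomyographic (MMG) recordings of
    levator ani muscle (pelvic floor) contractions acquired with a
    151-sensor SQUID array alongside surface EMG and ECG channels.
    Implements reference-channel frequency-dependent interference
    subtraction, band-pass and notch filtering, ICA-based artifact
    removal, trigger-locked epoching with baseline correction, SNR-gated
    quality control, amplitude and spectral feature extraction
    (sliding-window RMS, Welch power spectral density, band-normalised
    relative PSD), and paired pregnancy-versus-postpartum statistics.
    Includes a protocol-faithful synthetic session generator with known
    ground truth so every pipeline stage is testable without access to
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    ica,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'channels.R'
    'utils.R'
    'epochs.R'
    'features.R'
    'io.R'
    'mmglam-package.R'
    'stats.R'
    'subtr.R'
    'preprocess.R'
    'pipeline.R'
    'simulate.R'
    'study.R'
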