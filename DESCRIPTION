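Package: snailfs
Title: Brute-Force and Spiral-Ranked Feature Selection for Myoelectric
    Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-domain surface-EMG feature extraction (time, frequency,
    time-frequency, fractal and spatial descriptors), exhaustive
    mono-to-tetra brute-force feature-combination search scored by
    subject-wise repeated SVM cross-validation, and the SNAiL
    semi-brute-force spiral amalgamation that grows superior feature sets
    (5 to 20 features) from quintile-ranked brute-force pools with a
    golden-ratio (1.618) magnification factor. Includes a synthetic
    hemiplegic-EMG generator emulating low-channel stroke recordings, a
    preprocessing chain (zero-phase Butterworth bandpass, Hampel
    despiking, RMS normalization, peak-locked gesture windowing), eight
    canonical baseline feature sets and a one-tailed unpaired t-test
    comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
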