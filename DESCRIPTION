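Package: posturekit
Title: Wearable-Sensor Posture and Gait Recognition Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for recognising human postures and gait modes from wearable
    sensors. Detects active surface-electromyography (sEMG) segments with a
    moving-average energy threshold, extracts time-domain and wavelet features
    (standard deviation, singular values of discrete-wavelet-transform
    subbands, wavelet-packet energy spectra, forefoot-heel pressure
    difference), and classifies with a multiclass radial-basis-function
    support vector machine whose penalty factor and kernel width are tuned by
    a genetic algorithm scored with cross-validated accuracy. Includes
    synthetic generators for burst-like sEMG gesture trials and quasi-periodic
    five-mode gait trials, plus end-to-end experiment pipelines with tidy
    evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
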