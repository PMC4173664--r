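Package: psychsig
Title: Psychophysiological Signal Analysis for Ambulatory Affect Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring affective states from wearable
    psychophysiological recordings: heart-rate-variability feature
    extraction from ECG (Pan-Tompkins QRS detection, Berger resampling,
    time/frequency/Poincare/entropy features), continuous decomposition
    of skin conductance into tonic and phasic components by deconvolution
    with the Bateman impulse response, motion-artifact gating from finger
    flexion and accelerometer channels, arousal classification with PCA
    and a linear discriminant under repeated 80/20 validation, and
    classical-conditioning statistics (latency, first-interval SCR,
    HRV trends). Includes a synthetic-data generator with known ground
    truth emulating picture-viewing and conditioning protocols, so the
    whole pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    MASS,
    car,
    nortest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
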