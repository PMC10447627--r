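Package: sonokin
Title: Joint Kinematics Regression from A-Mode Ultrasound Sonomyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline mapping 1-D A-mode ultrasound echo
    signals recorded from the residual limb of transfemoral prosthesis users
    to knee and ankle position and velocity during walking. Implements the
    envelope-based reduction of each 997-sample frame to 48 windowed-mean
    features, round-robin assembly of 192-feature vectors across four
    sequentially sampled channels, per-variable multilayer-perceptron
    regressors, and an evaluation suite covering normalized RMSE, causal
    Butterworth filtering, cross-correlation delay estimation, gait-cycle
    averaging, peak-timing and range metrics. A seeded synthetic-data module
    generates trials with periodic gait kinematics and echo trains whose
    reflector depths deform with gait phase, standing in for non-deposited
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
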