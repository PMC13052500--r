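Package: kcscreen
Title: Keratoconus Screening from Polarization-Sensitive OCT and Corneal Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for three-class keratoconus
    screening (healthy, subclinical, manifest) from polarization-sensitive
    optical coherence tomography (PS-OCT) en-face maps and Scheimpflug /
    Placido-OCT tomography indices. Provides a synthetic cohort generator
    with class-conditional corneal phenotypes, PS-OCT signal math (reflectivity
    and phase retardation from orthogonal-channel amplitudes), Zernike
    decomposition of corneal maps, device-specific feature schemas, per-device
    random-forest classifiers evaluated by leave-one-out cross-validation, and
    cross-device agreement, reclassification and proportion-test utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
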