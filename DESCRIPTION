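Package: chiralflow
Title: Chiral Actomyosin Cortical Flows and Cell-Division Skews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies chiral actomyosin cortical flows and spindle skews
    in early embryonic cell divisions. Provides multi-pass particle image
    velocimetry for cortical fluorescence movies, chiral flow statistics
    (counter-rotating, net-rotating and contractile flow velocities with
    handedness), myosin intensity-profile extraction and step-plus-Gaussian
    fitting, a thin-film active chiral fluid solver that predicts
    counter-rotating flows from myosin distributions, torque-balance and
    geometric models relating counter-rotating flows to division skews,
    spindle-pole tracking with skew and elongation kinematics, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without raw microscopy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
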