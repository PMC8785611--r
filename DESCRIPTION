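Package: posturolab
Title: Force-Plate Posturography: Static Sway, Perturbation Recovery, and
    Dual-Task Cost Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual force-plate balance recordings.
    Builds the force-weighted center-of-pressure (CoP) trajectory from two
    plates, computes static sway outcomes (95% prediction-ellipse area, mean
    CoP velocity), segments platform-perturbation responses and measures
    recovery time from a velocity envelope, detects compensatory steps from
    single-plate unloading, computes motor and cognitive dual-task costs,
    and compares groups with nonparametric statistics after single-pass
    interquartile-range outlier removal. Includes a seeded synthetic cohort
    generator (Ornstein-Uhlenbeck sway plus perturbation transients) used by
    the analysis scripts and the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
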