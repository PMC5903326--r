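Package: fbcsp
Title: Filter-Bank Common Spatial Patterns with Particle Swarm Feature
    Selection for Motor-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for a two-class (rest versus hand motor imagery)
    electroencephalography brain-computer interface: a six-subband temporal
    filter bank with a 60 Hz notch, common spatial pattern (CSP) feature
    extraction via the generalized eigendecomposition of class covariance
    matrices, particle swarm optimisation of a multi-objective feature-subset
    fitness, linear discriminant classification, repeated stratified
    cross-validation against a broadband CSP baseline, an online-session
    simulator with a 2-of-3 robotic-orthosis trigger rule, and
    practical-level-of-chance statistics. Includes a seeded synthetic
    Graz-paradigm EEG generator with a controllable event-related
    desynchronization so the full chain is testable without recordings.
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
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
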