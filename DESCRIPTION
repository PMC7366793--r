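Package: synact
Title: Synergy-Constrained and Static Optimization for the Muscle
    Redundancy Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating lower-limb muscle activations during
    gait from inverse-dynamics joint moments under a rigid-tendon
    Hill-type muscle model. Implements per-frame static optimization
    with exact moment-matching equality constraints (SO), all-frame
    synergy optimization with B-spline parameterized synergy
    activations and sum-to-one synergy vectors (SynO), and non-negative
    matrix factorization of static-optimization activations with
    L1-normalized synergy vectors (SO-NMF), together with EMG envelope
    processing, variance-accounted-for (VAF) and lagged Pearson
    correlation metrics, and a seeded synthetic trial generator with
    known ground-truth synergy structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
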