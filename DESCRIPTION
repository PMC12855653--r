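Package: gazerp
Title: Joint Eye-Movement and ERP Analysis of Masked Face Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for studying how face masks change own- and
    other-race face processing with simultaneous eye tracking and EEG.
    Fits per-participant scanpath hidden Markov models with variational
    Bayesian model selection, clusters them into representative
    eyes-focused and nose-focused patterns, and scores participants on a
    normalized log-likelihood (eyes-nose) scale and on scanpath entropy.
    Quantifies P1, N170 and P2 event-related potential components,
    performs sliding-window multivariate decoding of face race and
    identity from scalp voltages with cluster-based permutation
    inference, and computes the group-level mask-effect statistics.
    Includes a synthetic-cohort generator with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
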