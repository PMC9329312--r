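Package: kinomescreen
Title: Kinome-Wide Screening of Kinase Inhibition Against Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Relates small-molecule kinase-inhibitor exposure to
    time-to-adverse-event outcomes. Builds drug-agnostic per-patient
    kinase-inhibition features from steady-state plasma concentrations and
    kinome dissociation constants, screens kinase-adverse-event associations
    kinome-wide with random survival forests (log-rank node splitting,
    Nelson-Aalen terminal-node cumulative hazards, permutation variable
    importance and minimal depth), and evaluates predictions with
    concordance-based bootstrap and leave-one-out cross-validation, external
    validation at an incidence threshold, and reporting odds ratios. Includes
    a synthetic-data generator with known causal structure so the whole
    pipeline can be exercised end-to-end without access to confidential
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ranger,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
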