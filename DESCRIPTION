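Package: comboscreen
Title: Simulation and Machine-Learning Analysis of Drug Combination
    Synergy Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing all-vs-all drug combination matrix screens
    of the kind used to discover synergistic anti-cancer drug pairs. The
    package simulates a full combination screen (compound library,
    single-agent potencies, duplicate 10x10 dose-response matrices and
    gamma-style synergy scores with a known mechanism-of-action ground
    truth), featurizes compound pairs (circular and path fingerprints,
    physicochemical descriptors, mechanism-of-action vectors, mixture
    graphs), runs combination-aware cross-validation (one-compound-out and
    everything-out) with Y-randomization controls, fits bagged-tree,
    boosted-tree and feed-forward network learners plus a multi-task
    Bliss-residual surrogate model, combines them into consensus scores,
    nominates top candidate combinations under three strategies, and tests
    mechanism-of-action co-occurrence among synergistic combinations with
    a permutation null.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
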