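Package: elraqsp
Title: Quantitative Systems Pharmacology Virtual Trials for a BCMA-CD3 Bispecific in Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic three-compartment model of bispecific T-cell-engager
    (CD3 x BCMA) trimer kinetics, tumor killing and paraprotein dynamics in
    relapsed/refractory multiple myeloma, together with the virtual-population
    workflow built around it: log-normal baseline sampling with a soluble-BCMA
    drug-sink stratification, plausibility filtering by untreated doubling
    times, genetic-algorithm selection of 120-patient virtual populations
    against cohort-level calibration targets, IMWG-derived biochemical response
    scoring, and virtual-trial experiments (dose-response by baseline soluble
    BCMA, binding-ratio curve-shape taxonomy, adaptive dose-frequency
    de-escalation, and logistic-regression biomarker threshold scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
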