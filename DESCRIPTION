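Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analyses of FAERS-style
    quarterly spontaneous-report data: ingestion of dollar-delimited DEMO, DRUG,
    REAC, THER, INDI and OUTC tables, FDA-recommended deduplication by CASEID,
    FDA_DT and PRIMARYID, primary-suspect cohort construction from a drug
    dictionary, preferred-term to organ-class aggregation, disproportionality
    signal detection with the reporting odds ratio, the proportional reporting
    ratio with Pearson chi-squared, and the Bayesian information component,
    a triple-algorithm consensus rule with expectedness flagging against a
    label-term list, Weibull time-to-onset modelling with hazard-type
    classification, and baseline demographic tabulation.  A synthetic report
    generator with planted drug-event signals of known strength makes every
    stage testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    survival,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
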