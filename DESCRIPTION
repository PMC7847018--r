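Package: crrtpk
Title: Pharmacokinetics and Dialytic Clearance Analysis for In Vitro CRRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro continuous renal replacement
    therapy (CRRT) drug-clearance experiments, built around apixaban as the
    study drug. Implements noncompartmental pharmacokinetics (terminal slope,
    linear-up/log-down AUC), sieving and saturation coefficients,
    transmembrane clearance by AUC and by coefficient-times-flow-rate with an
    optional pre-dilution correction, hemofilter adsorption and plasma
    protein-binding estimation, factorial ANOVA with estimated marginal means
    and Tukey contrasts, backward-stepwise regression of clearance on circuit
    covariates, and target-exposure dose optimization producing rounded
    twice-daily regimens. A circuit simulator generates synthetic experiments
    with known parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    deSolve,
    dplyr,
    emmeans,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
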