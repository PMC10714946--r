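Package: tirzepk
Title: Whole-Body Pharmacokinetic Modelling of Tirzepatide with Pediatric Dose Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and calibrates a whole-body physiologically based
    pharmacokinetic (PBPK) model of once-weekly subcutaneous tirzepatide in
    adults, extrapolates it to virtual pediatric populations (10-18 years,
    normal-weight and obese), and searches candidate dose reductions whose
    pediatric exposure matches the adult reference range. Includes virtual
    individual and population generation with age- and sex-resolved organ
    volumes, blood flows and glomerular filtration rate; a first-order
    subcutaneous absorption depot feeding a flow-limited organ network with
    ubiquitous peptidase metabolism and renal elimination; non-compartmental
    analysis (AUC, Cmax, Tmax, terminal half-life, CL/F); fold-error and
    average-fold-error model qualification against published adult studies;
    seeded Monte-Carlo random-search calibration under a urinary-excretion
    constraint; and a synthetic trial generator with log-normal
    between-subject and residual variability.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
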