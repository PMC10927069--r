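Package: elma
Title: Expected Labor Market Affiliation from Multi-State Event Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates expected days spent in seven labor-market states
    (work, sickness absence, unemployment, temporary out, retirement,
    disability pension, death) over a two-year follow-up as a function of a
    0-3 work-stress indicator count, using transition-specific Cox
    proportional-hazards models, product-integral (Aalen-Johansen) transition
    probabilities and area-under-the-curve state durations with resampling
    confidence intervals. Converts duration differences into annualized
    absenteeism costs from individual hourly wages (human-capital approach)
    with wage standardization, truncation, regression imputation and
    price indexing. Ships a register-style synthetic-cohort generator with
    known transition intensities so the full pipeline is testable against a
    closed-form Markov oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    MASS,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
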