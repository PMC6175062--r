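Package: copropk
Title: Population Pharmacokinetics of Coproporphyrin I as an Endogenous
    OATP1B Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semimechanistic population-pharmacokinetic toolkit for
    coproporphyrin I (CPI), an endogenous probe of hepatic OATP1B transport.
    Implements structural models for oral rifampicin (transit-compartment
    absorption, one-compartment disposition), CPI (turnover model with
    biliary and renal elimination and competitive inhibition of biliary
    clearance by rifampicin) and rosuvastatin (two-compartment first-order
    absorption); an exponential inter-individual/inter-occasion
    random-effects layer with combined proportional-additive residual
    error; a synthetic three-occasion crossover-trial generator in a
    NONMEM-like long format; Laplace-approximation maximum-likelihood
    estimation with sequential perpetrator-first fitting, empirical Bayes
    estimates, visual predictive checks and profile-likelihood
    identifiability diagnostics; noncompartmental metrics (trapezoid AUC,
    AUC ratios, transporter-mediated fraction fT); and forward
    drug-drug-interaction simulation with simulation-based power and
    sample-size calculations for crossover biomarker studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
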