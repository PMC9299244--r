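Package: vaxeval
Title: Empirical Evaluation of Vaccine Safety Surveillance Designs on Synthetic Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal observational health data (persons,
    observation periods, outpatient visits, vaccinations, outcome
    occurrences) with known vaccine-outcome effects and configurable
    confounding through latent frailty and health-seeking behaviour, then
    evaluates epidemiological safety-surveillance designs against that
    known truth. Implements the historical comparator, concurrent cohort
    (propensity-score matched, stratified and weighted), case-control and
    self-controlled (SCCS/SCRI) design families under monthly sequential
    looks, maximum sequential probability ratio testing (MaxSPRT) with
    Monte-Carlo critical values, empirical calibration of p-values and
    log-likelihood ratios from negative-control outcomes, and performance
    metrics: type 1 and type 2 error and time to 50% sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    survival,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
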