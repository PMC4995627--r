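Package: raschtraj
Title: Scoring Changing Questionnaires for Trajectory Analysis in
    Long-Term Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for comparing ways of scoring a
    questionnaire that changes during long-term cohort follow-up. Cohorts of
    binary item responses are generated from a longitudinal Rasch model with
    group-specific latent trajectories; raw sum scores over shared items,
    per-time standardised scores, and Rasch latent-variable scores (item
    difficulties estimated by conditional or marginal maximum likelihood with
    across-time equality constraints, person levels by WLE, EAP or ML) are
    computed under configurable item-sharing scenarios; latent class growth
    analysis (LCGA) is fitted to each measure by a multi-start EM algorithm;
    and recovery of the true trajectory groups is evaluated by percentage
    correctly classified, Cohen's kappa and relative entropy over Monte Carlo
    replicates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    parallel,
    pracma,
    purrr,
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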