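Package: injurybn
Title: Bayesian Network Modelling of Stress-Related Injury Risk in Athlete Cohorts
Version: 0.1.0
Authors@R: person("Harri", "Edwards", email = "harri.edwards@example.org",
    role = c("aut", "cre"))
Description: Tools for interdisciplinary analysis of psychosocial and
    physiological stress markers and sports-injury occurrence in
    longitudinal athlete cohorts.  Provides instrument scoring (life-event
    surveys, reinforcement-sensitivity personality subscales, RMSSD heart
    rate variability from inter-beat intervals, myometric muscle stiffness,
    balance error scoring), repeated-measures data preparation (bagged-tree
    imputation, cumulative log-scaled life events, median-split
    discretisation, two-time-slice and standardised change-score tables),
    discrete and conditional-linear-Gaussian Bayesian network structure
    learning (Tabu search with BIC scoring, blacklist/whitelist
    constraints, bootstrap arc-strength model averaging), network inference
    (Markov blankets, likelihood-weighted conditional probability queries,
    evidence-grid tables, Bayesian linear regression on network-drawn
    samples), and a synthetic cohort generator with a known ground-truth
    dependency structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
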