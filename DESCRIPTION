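Package: moodcast
Title: Hierarchical Bayesian Forecasting of Daily Mood from Smartphone Self-Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts daily self-reported mood in bipolar disorder from short
    histories of smartphone self-assessment questionnaires. Implements
    hierarchical Bayesian linear and ordered-logistic regression with partial
    pooling across patients (MCMC via JAGS), the questionnaire preprocessing
    steps (medicine dummy coding, sleep splitting around the individual mean,
    min-max normalisation), windowed design-matrix construction over a
    history of w days at forecast horizon h, two time-series cross-validation
    schemes (leave-all-out and leave-one-out), naive and machine-learning
    baselines, posterior-predictive tail checks, feature importance, and a
    seeded synthetic cohort generator for end-to-end testing without access
    to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
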