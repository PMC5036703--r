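Package: caresem
Title: Bayesian Structural Equation Models for Primary-Care Quality, Access
    and Unplanned Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian multiple-indicator multiple-cause (MIMIC)
    structural equation models in which latent primary-care quality and
    latent poor access, each measured by overdispersed binomial indicators,
    predict unplanned hospital admission counts alongside deprivation,
    morbidity and supply covariates. Provides synthetic-data generation from
    the generative model, adaptive Metropolis-within-Gibbs inference,
    component-wise WAIC, posterior predictive checks, marginal Bayes
    factors, locally weighted factor-versus-risk summaries, and aggregation
    of practice-level scores to small-area geographies via population
    crosswalks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
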