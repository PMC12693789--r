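Package: firipm
Title: Bayesian Integral Projection Models for a Declining Subalpine Fir Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate size-dependent vital rates (survival, growth,
    recruitment) from biennial tree census data with Bayesian regression models,
    assemble discretised integral projection model (IPM) kernels with eviction
    correction, compute the population growth rate lambda with posterior
    uncertainty, project future diameter distributions, derive the SPEI-24
    drought index from monthly weather via FAO-56 Penman-Monteith reference
    evapotranspiration and a log-logistic standardisation, relate log lambda to
    drought with a Bayesian observation-error regression, and rank vital-rate
    parameters and size classes by their influence on lambda using a
    gradient-boosted surrogate with SHAP values and perturbation elasticities.
    Includes a synthetic census and weather generator so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    zoo
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
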