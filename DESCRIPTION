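Package: raygrowth
Title: Age and Growth Estimation for Data-Poor Elasmobranchs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-stage estimation of growth parameters from size-at-age
    data for data-poor elasmobranch populations. Provides four standard
    growth functions (von Bertalanffy, two-parameter von Bertalanffy,
    logistic and Gompertz), Ford-Walford starting values, nonlinear
    least-squares fitting with bias-corrected AIC (AICc) model ranking,
    Bayesian estimation of the two-parameter von Bertalanffy model by
    Metropolis-Hastings sampling under informative priors with Geweke
    convergence diagnostics, multi-reader ageing precision indices (IAPE
    and CV), a synthetic size-at-age and reader-matrix generator, and a
    simulation study comparing least-squares and Bayesian estimators
    under data-poor sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
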