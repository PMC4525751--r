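Package: clustrisk
Title: Marginal and Conditional Risk Prediction from Random-Intercepts
    Logistic Models for Clustered Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits logistic models to clustered binary outcomes by three
    routes (standard maximum likelihood ignoring clustering, random
    intercepts via Gauss-Hermite quadrature, and generalised estimating
    equations with an exchangeable working correlation) and computes
    population-average predicted risks from the random-intercepts fit
    either naively (random effects set to zero), by integrating over the
    estimated random-effects distribution, or by rescaling the conditional
    coefficients with the Zeger attenuation factor.  Conditional
    (cluster-specific) predictions use the posterior distribution of the
    cluster random effect.  Includes calibration assessment
    (calibration-in-the-large and calibration slope), a synthetic-data
    generator for a clustered source population with two-stage sampling of
    training sets, and an orchestrated simulation study comparing the
    calibration of the marginal prediction methods across degrees of
    intra-cluster correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
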