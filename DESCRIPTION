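Package: bymlogit
Title: Bayesian Spatial Multilevel Logistic Models with CAR Random Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian multilevel logistic regression models for binary
    health outcomes (such as obesity) on individuals nested in small areas,
    with an intrinsic conditional autoregressive (CAR) spatial random effect
    and an independent heterogeneity effect on the logit scale (the
    Besag-York-Mollie convolution). Provides four nested model variants,
    Metropolis-within-Gibbs posterior sampling, odds-ratio summaries with
    credible intervals, deviance information criterion (DIC) model
    comparison, the spatial-fraction variance partition, a univariate
    logistic screening stage with stratified descriptive tables, GIS-style
    built-environment metrics (grid distances to destinations, densities,
    land-use-mix entropy, tertiles), and synthetic-data generators for
    landscapes and nested cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    rjags,
    yaml
Config/testthat/edition: 3
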