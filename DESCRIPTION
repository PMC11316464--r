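Package: foramenflow
Title: Femoral Blood Flow from Nutrient Foramina and Phylogenetic
    Comparative Analysis of Aerobic Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates volumetric blood-flow rate through the femoral
    nutrient artery from foramen measurements, and analyses its allometric
    scaling across mammals with phylogenetic comparative methods on
    time-scaled, possibly non-ultrametric trees. Provides univariate
    Brownian-motion, Ornstein-Uhlenbeck and white-noise model fits with
    Akaike-weight selection, phylogenetic generalized least squares with an
    OU (Martins-Hansen) correlation structure, phylogenetic ANCOVA with
    Bonferroni-adjusted pairwise intercept contrasts, Cholesky-whitened
    residual normality checks, and a multivariate Ornstein-Uhlenbeck model
    for joint trait evolution used to impute maximum metabolic rate at
    fossil tips and reconstruct ancestral states with confidence intervals.
    A seeded synthetic-data generator produces trees, taxon traits and
    specimen tables with the statistical structure the analyses assume, so
    the whole pipeline is testable without museum data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    jsonlite
Suggests:
    nlme,
    nortest,
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
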