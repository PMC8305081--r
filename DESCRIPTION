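Package: fermkin
Title: Fermentation Kinetics and Starter-Culture Response Modelling for
    Cereal Beverages
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Primary predictive-microbiology models for lactic acid
    fermentation of cereal slurries: exponential acidification kinetics for
    pH and titratable acidity, quadratic sugar kinetics, the modified
    Gompertz growth model for bacterial counts with the mean relative
    deviation modulus as goodness of fit, plateau (optimum fermentation
    time) detection from replicate summary statistics, a factorial
    generalized linear model with Wald inference for starter-culture
    inoculum effects, and Monte Carlo uncertainty propagation with
    tornado-style sensitivity ranking. Includes seeded synthetic-data
    generators for both experimental layouts, bundled reference datasets,
    and an end-to-end analysis pipeline with a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
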