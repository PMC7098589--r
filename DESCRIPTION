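Package: elastax
Title: Simulating Food Tax and Subsidy Policies with Price-Elasticity
    Matrices and Total-Food-Expenditure-Elasticity Rescaling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating the dietary and health impacts of food
    taxes and subsidies. Price changes are propagated through a Marshallian
    conditional price-elasticity matrix, rescaled to respect the
    conditional (fixed total food expenditure) assumption, and then
    reallocated with food-group expenditure elasticities so that total
    food expenditure moves according to a total food expenditure
    elasticity (TFEe). Includes disaggregation of aggregate elasticity
    matrices to finer food lists under an adding-up constraint, a
    simplified diet to BMI to disease to health-adjusted-life-year chain
    via a proportional multistate lifetable, Monte-Carlo uncertainty
    propagation, univariate sensitivity analysis, synthetic food-system
    generators for testing, and CSV/YAML/JSON interchange with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
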