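Package: fortintake
Title: Estimation and Comparison of Fortifiable Food Vehicle Consumption
    from Household and Individual Dietary Instruments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the consumption of fortifiable food
    vehicles (wheat flour and edible oil) from three dietary assessment
    instruments: a household food acquisition and purchase questionnaire
    apportioned to individuals with the adult-male-equivalent method, a
    7-day semiquantitative food frequency questionnaire quantified
    against an item table of flour gram equivalents, and repeated 24-hour
    recalls aggregated to person-day vehicle amounts and adjusted for
    within-person variation with an amount-only measurement-error model
    (Box-Cox transformation, person-level random effects, Gauss-Hermite
    back-transformation).  Includes the method-comparison machinery
    (outlier exclusion, matched-observation filtering, summary
    statistics, ratio and percent differences, food-source
    decomposition), WHO flour-intake-category fortification decision
    rules, and a synthetic-data generator with known ground truth for
    validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
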