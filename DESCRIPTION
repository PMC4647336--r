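Package: physupply
Title: Spatial Economic Modelling of Outpatient Physician Supply
Version: 0.1.0
Authors@R: person("physupply", "developers", role = c("aut", "cre"),
    email = "physupply@example.org")
Description: Tools for studying regional differences in outpatient physician
    supply. Implements a two-region (urban/rural) economic model of physician
    practice location in which Cobb-Douglas consumers face money and time
    budgets, per-visit time costs fall with physician density, and physicians
    allocate across regions until incomes equalize up to a regional preference
    weight. The accompanying empirical toolkit fits zero-truncated
    negative-binomial generalized linear models of district-level general
    practitioner and specialist counts with a log population offset, regional
    association (ASHIP) intercepts and two-standard-deviation covariate
    standardization, runs a cross-model backward stepwise selection with a
    keep-if-significant-anywhere rule, and back-transforms coefficients into
    physician densities per 10 000 inhabitants. A seeded synthetic district
    generator emulating published covariate distributions makes the whole
    pipeline testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
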