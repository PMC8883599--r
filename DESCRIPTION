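Package: dairylp
Title: Linear-Programming Analysis of Non-Dairy Replacements for Dairy Nutrients
Version: 0.1.0
Authors@R: person("dairylp", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and solves the diet-optimisation linear programme that
    finds combinations of non-dairy food categories replacing the protein and
    ten shortfall nutrients (Ca, choline, fibre, Fe, Mg, K, vitamins A, C, D,
    E) in USDA cup-equivalent servings of dairy, while minimising cost, energy
    or food weight. Includes survey-weighted intake percentiles for
    consumption caps, CPI inflation adjustment and mixed-dish component cost
    regression, binding (limiting) nutrient analysis, reference-serving
    (RACC) reporting, and a seeded synthetic-data generator emulating
    WWEIA-style food category, price and 24-h recall intake tables so the
    whole pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
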