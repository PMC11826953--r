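Package: compsleep
Title: Compositional and Isotemporal Substitution Analysis of Diet and Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the macronutrient composition of the diet
    relates to objectively measured sleep. Implements energy-weighted closure of
    macronutrient intakes onto the unit simplex, additive and isometric log-ratio
    transforms with default and per-nutrient pivot balance bases, the variation
    matrix and compositional mean, proportional reallocation and one-to-one
    isotemporal substitution of energy shares, and ordinary least squares
    regression with prediction-difference confidence intervals built from the
    residual standard error, model matrix and t critical values. A seeded
    synthetic cohort generator emulates a large app-based cohort (logistic-normal
    compositions, moment-matched sleep outcomes, plantable balance effects) so
    the full pipeline -- exclusion cascade, quartile dummy regression,
    compositional reallocation tables and isotemporal substitution tables -- can
    be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lmtest,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
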