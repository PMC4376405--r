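Package: rutfoptim
Title: Least-Cost Formulation and Nutrient Evaluation of Ready-to-Use
    Therapeutic Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing ready-to-use therapeutic foods (RUTFs)
    from local plant ingredients by least-cost linear programming.
    Builds and solves cost-minimizing blend formulations under
    nutrient-density and ingredient-level constraints, evaluates
    formulations by linear nutrient blending, Atwater energy and
    carbohydrate-by-difference, compares software-predicted with
    laboratory-measured composition, computes the product intake
    needed to meet daily nutrient requirements with identification of
    the limiting nutrient, and tracks ingredient-cost trends across
    years. Ships a worked Mali case study (ingredient prices
    2004-2009, six peanut/cowpea/millet/koji formulations and their
    measured composition) plus a synthetic-instance generator with a
    brute-force grid-enumeration oracle for solver verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
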