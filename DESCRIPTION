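Package: lassikin
Title: Mixture-Design Optimization and Storage Degradation Kinetics for
    Functional Beverages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the two-stage quality analysis of formulated food
    products, developed around a microgreens-based fermented dairy (lassi)
    beverage.  Stage one fits Scheffe mixture polynomials (linear, quadratic,
    special cubic) in L-pseudo-component coding to constrained
    three-component mixture designs, selects D-optimal run subsets by
    Fedorov exchange, and locates optimal formulations by Derringer
    desirability.  Stage two fits zero-, first- and second-order degradation
    kinetics to multi-temperature storage series, models the temperature
    dependence of rate constants with the Arrhenius, Eyring and Ball
    equations, and predicts shelf life (half-life, D-value, Z-value).
    Includes assay conversion formulas, packaged study fixtures, and a
    synthetic-data generator with known ground truth for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
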