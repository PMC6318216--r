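Package: bcef
Title: Least-Squares and Ratio Estimation of Biomass Conversion and
    Expansion Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates biomass conversion and expansion factors (BCEFs),
    the proportionality constants converting stem volume (m^3) to tree
    component dry biomass (Mg), by least-squares regression through the
    origin and by classical ratio estimators, and compares the two
    approaches with a full model-score card: Akaike information
    criterion, slope standard error, coefficient of variation of the
    residuals, Furnival's index of fit, the hat-matrix mean quadratic
    error of prediction (PRESS/n), and K-fold cross-validated prediction
    error. Includes reduction of raw felled-tree measurements (Hohenadl
    sectional stem volume, disc-based dry-mass scaling), residual
    normality gating with a Gamma GLM fallback, the intercept-zero test
    that justifies regression through the origin, and a seeded synthetic
    population generator for mopane and miombo timber species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
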