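Package: vicombo
Title: Sex-Specific Drug Combination Optimization for Valvular
    Interstitial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analysing low-dose drug combination
    screens against myofibroblast activation in valvular interstitial
    cells (VICs). Implements constrained four-parameter logistic
    dose-response fitting with absolute EC/CC values, clinically bounded
    dose-level selection, construction and validation of a 59-run
    resolution-IV orthogonal array composite design (OACD) for eight
    drugs at three levels, second-order quadratic response-surface
    modelling via F-test stepwise regression with Box-Cox transform
    selection and studentized-residual outlier screening, exhaustive
    ranking of all 6561 level combinations, male-female sex-bias
    differencing, and Bliss-independence synergy scoring of checkerboard
    dose matrices. A seeded synthetic-data generator emulates the
    statistical structure of the wet-lab measurements so that every
    stage of the pipeline can be verified in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
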