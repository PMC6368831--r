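Package: nichecal
Title: Detailed Calibration, Projection and Extrapolation-Risk Analysis for
    Ecological Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for rigorous ecological niche modelling
    (ENM): exhaustive candidate-model calibration over regularization
    multipliers, feature-class combinations and predictor sets; hierarchical
    model selection by partial-ROC significance, omission rate at threshold E
    and AICc; final-model fitting with bootstrap replicates and transfers to
    multiple scenarios under free, clamped and no-extrapolation regimes;
    evaluation with independent occurrence data; and extrapolation-risk
    surfaces via the mobility-oriented parity (MOP) and MESS metrics. A
    built-in Maxent-style penalized Gibbs model engine (linear, quadratic,
    product, threshold and hinge features with L1 regularization solved as a
    weighted lasso logistic regression) removes the need for the external
    Maxent Java program, and a virtual-species simulator provides fully
    reproducible test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
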