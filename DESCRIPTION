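Package: itgrow
Title: Individual-Tree Growth Modelling with Covariate-Parameterized
    Mitscherlich Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits individual-tree diameter and height growth models for
    repeatedly measured forest-inventory plots. The core model is a
    Mitscherlich growth curve whose asymptote and rate parameters are linear
    combinations of competition (plot density), site (elevation, slope
    position, soil) and annual climate covariates, estimated by nonlinear
    least squares. Around it the package provides grouped 3-sigma (Pauta)
    outlier filtering, variance-inflation and AIC-stepwise covariate
    screening, random-forest impurity importance with Pearson correlation
    screening, back-propagation network and random-forest baselines over a
    nested covariate ladder, fit metrics and residual diagnostics, and a
    synthetic inventory generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    nnet,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    car,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
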