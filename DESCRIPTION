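Package: palpquant
Title: Quantification of Stiff Nodule Size and Depth from Instrumented Palpation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative instrumented palpation of soft tissue.
    Implements a 2D plane-strain hyperelastic finite-element forward model of
    rigid frictionless indentation on a tissue block with an embedded stiffer
    nodule, smoothing-spline second-derivative analysis of force-feedback
    profiles, a calibration-library inversion that decouples nodule size from
    nodule depth using measurements at several indentation depths, Ogden and
    neo-Hookean constitutive models with Levenberg-Marquardt material
    identification, and synthetic tissue-phantom generators with configurable
    measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
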