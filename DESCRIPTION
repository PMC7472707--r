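Package: spatlogit
Title: Bayesian Spatial Logistic Regression for Areal Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Survey-weighted Bayesian logistic regression for individual-level
    outcomes nested in areal units, with an intrinsic CAR (Besag) spatial random
    effect, an IID unstructured district effect (BYM convolution), and random-walk
    (RW1/RW2) smoothing priors for nonlinear effects of continuous covariates.
    Inference is by Polya-Gamma Gibbs sampling. Includes WAIC model comparison,
    covariance-structure and backward covariate selection, prior-sensitivity
    sweeps, generalized variance inflation factor (GVIF) screening, descriptive
    tables, exceedance-probability risk mapping, and a synthetic areal survey
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    glmmTMB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
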