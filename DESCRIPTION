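Package: fracpde
Title: Discovery of Reaction-Diffusion Equations with Rational, Power and
    Integral Interaction Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns the right-hand side of two-component reaction-diffusion
    systems from noisy gridded observations.  Spatial derivatives are
    represented by trainable convolution kernels whose moment matrices are
    partially constrained to guarantee at least second-order accuracy; the
    reaction terms are represented by a symbolic network whose hidden units
    are multiplications or divisions of learned linear combinations of
    library channels, extended with a trainable fractional power u^alpha and
    a spatial integral channel.  The trained network is expanded into an
    explicit symbolic expression, sparsified by an L2-norm term selection
    criterion followed by sequential-threshold ridge regression (STRidge),
    and the coefficients of the retained structure are retrained.  A
    post-hoc parsimony check compares the final model against a reduced one
    with per-time two-sample bivariate Kolmogorov-Smirnov tests under
    multiple-testing adjustment.  Includes finite-difference generators for
    two benchmark systems (a 2-D activator-depletion model and a 1-D
    cell-polarity model with a non-local integral term) so the whole
    pipeline runs from synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
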