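Package: diffsurr
Title: Neural-Network Surrogates for Steady-State Diffusion Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and evaluates convolutional neural-network surrogates of
    the steady-state diffusion equation with constant-value disk sources in a
    square domain with absorbing boundaries. Provides a sparse finite-difference
    solver for generating paired source-layout/steady-field training data, a
    dual-branch surrogate (a size-preserving deep CNN combined with a
    convolutional autoencoder), an exponentially weighted MAE/MSE loss that
    compensates for the rarity of high field values, roll-back training that
    reverts checkpoint state after stochastic loss spikes, residual-based
    evaluation metrics (pooled summaries, value-slice statistics, field-value
    densities), and a break-even model for the amortization of surrogate
    construction cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
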