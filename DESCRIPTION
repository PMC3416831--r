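Package: stokinfit
Title: Moment Fitting for Parameter Inference in Stochastic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring reaction rate constants of stochastic
    biochemical networks from repeated, partially observed time-series data.
    Exact realizations of the jump process are generated with the Gillespie
    direct method, per-time sample moments are computed across replicates, and
    closed parameter-dependent ODE systems for the theoretical moments (exact
    equations for affine propensities, one-dimensional normal moment closure,
    and the multivariate linear noise approximation) are solved numerically.
    Rate parameters are estimated by minimizing weighted moment-residual cost
    functions with adjoint-method gradients via trust-region-style nonlinear
    least squares, or sampled by Metropolis random-walk MCMC. Hessian
    eigen-decompositions quantify parameter sloppiness and identifiability.
    Built-in test models include a linear birth-death process, dimerisation
    kinetics, and a p53-Mdm2 feedback loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
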