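Package: pohmm
Title: Poisson Hidden Markov Models with Exact-Derivative Likelihood Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood estimation of stationary Poisson hidden Markov
    models for univariate count series. The scaled forward algorithm is
    implemented in C++ together with analytic first and second derivatives of
    the negative log-likelihood with respect to unconstrained working
    parameters (multinomial-logit transition probabilities, log conditional
    means), so quasi-Newton or full Newton optimization uses exact gradients
    and Hessians. Provides delta-method (Wald), profile-likelihood and
    parametric percentile-bootstrap confidence intervals, nested models via
    parameter constraint maps, posterior state decoding (smoothing and
    Viterbi), h-step-ahead forecast distributions, seeded model simulation and
    a Monte Carlo coverage-study harness, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
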