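Package: erdeconv
Title: Non-Parametric Bayesian Input Estimation for Extended-Release
    Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the in vivo absorption-rate profile and
    bioavailability of extended-release drug formulations from plasma
    concentration data, given a (possibly non-linear) pharmacokinetic
    model.  The absorption rate is modeled non-parametrically in the log
    domain on a truncated Karhunen-Loeve basis with a second-derivative
    smoothness prior, and the full posterior is recovered by Markov chain
    Monte Carlo, alternating simplified-manifold MALA updates of the
    basis coefficients with Gibbs updates of the regularization
    parameter.  Ships the target-mediated drug disposition (TMDD) model
    of exenatide, an algebraic steady-state shortcut for slowly varying
    inputs, robust Student-t proportional-error likelihoods, a synthetic
    validation-data generator, and a Raftery-Lewis chain-length
    diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
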