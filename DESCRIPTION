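Package: isingscape
Title: Stability Landscapes and Phase-Stability Metrics for Ising Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stability-landscape computation for Ising networks of
    binary symptom data. Enumerates the Boltzmann distribution over all
    microstates to obtain the steady-state distribution of the number of
    active nodes and its generalized potential U(n) = -log P(n), computes
    clinical-cutoff-anchored phase-stability metrics, estimates network
    parameters from person-by-symptom binary data by nodewise logistic
    regression, quantifies metric uncertainty with BCa bootstrap intervals
    and p-values, compares groups via stratified bootstrap, parameter-swap
    landscapes and permutation tests on symptom counts, and provides Glauber
    and exact samplers plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
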