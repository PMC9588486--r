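Package: dualphos
Title: Dual-Phosphorylation ERK Kinetics: Model Reduction, Identifiability
    and Topological Posterior Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action models of processive/distributive dual
    phosphorylation of ERK by MEK, algebraic quasi-steady-state reduction to
    the Rational and Linear ERK models, likelihood-based practical
    identifiability analysis (maximum-likelihood fits, simulated
    likelihood-ratio calibration, marginalised confidence regions), Bayesian
    posterior sampling of the reduced kinetic parameters, and topological
    comparison of posterior point clouds by persistent homology of kernel
    density super-level sets with bottleneck-distance hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
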