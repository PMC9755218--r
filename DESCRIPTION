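Package: sparsedyn
Title: Sparse Bayesian Discovery of Ordinary, Partial and Stochastic Differential Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers governing differential equations from trajectory and field
    data by sparse symbolic regression over candidate-function libraries.
    The core solver is automatic-threshold sparse Bayesian learning (ATSBL):
    a fast sequential evidence-maximization fit under a hierarchical Laplace
    (or Gaussian) prior, wrapped in a train/test thresholding loop that
    selects the sparsity level automatically.  For Langevin-type stochastic
    differential equations, drift and diffusion (Kramers-Moyal) coefficients
    are estimated either directly from trajectory increments or from binned
    statistics with entropy-based probability filtering.  An active-learning
    loop (AISO) iteratively applies a Gaussian-weighted control force opposing
    the inferred drift to drive trajectories out of metastable states and
    improve global model identification.  Benchmark generators (double-well,
    time-dependent and multi-well Langevin systems, the Lorenz system and a
    lambda-omega reaction-diffusion solver) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    data.table,
    jsonlite,
    signal,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
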