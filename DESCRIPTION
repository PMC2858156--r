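Package: nir
Title: Network Identification by Multiple Regression for Gene Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse-engineers gene regulatory networks from steady-state
    gene-expression responses to known perturbations using the NIR
    (Network Identification by multiple Regression) approach: for each
    gene a sparse multiple linear regression with at most k regulators is
    selected by a greedy beam search over candidate regulator sets, with
    each candidate evaluated through a precomputed Gram matrix and a
    Cholesky solve of the normal equations.  Includes an in-silico
    simulator of sparse stable linear networks and their noisy
    steady-state responses to single-gene perturbations, accuracy scoring
    (positive predictive value and sensitivity over directed, undirected
    or signed edge sets), a gene-parallel execution scheme with
    deterministic results, and a command-line interface wiring
    simulate, infer, evaluate and benchmark steps together.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
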