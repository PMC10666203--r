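Package: tissueABC
Title: Likelihood-Free Bayesian Inference for Stochastic Multicellular
    Lattice Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for estimating parameters of stochastic
    multicellular tissue models by approximate Bayesian computation with
    sequential Monte Carlo (ABC-SMC). Provides a tab-separated problem
    specification dialect (model document plus parameter, condition,
    measurement and summary-statistic tables) with a validator; a desk-scale
    lattice simulator comprising a cellular Potts kernel, an explicit
    reaction-diffusion virion field, and a two-route viral-spread model;
    summary statistics with robust adaptive distance weighting and
    inverse-regression summary construction; an ABC-SMC engine with adaptive
    epsilon schedules, Gaussian perturbation kernels, early rejection and
    static/dynamic scheduling contracts; and an append-only result store
    with posterior diagnostics (effective sample size, weighted credible
    intervals, weighted kernel density estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
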