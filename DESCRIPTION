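Package: specdcm
Title: Spectral Dynamic Causal Modelling of Anticorrelated Resting-State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how directed (effective) connectivity among
    resting-state brain networks generates their observed functional
    connectivity. Simulates multi-region BOLD time series from linear
    stochastic neuronal dynamics driven by power-law endogenous fluctuations
    and observed through a linearised haemodynamic response; estimates
    effective connectivity by fitting the complex cross-spectral density with
    a variational Laplace scheme; and provides second-level machinery
    (Bayesian model reduction, greedy model search, Bayesian model averaging,
    parametric empirical Bayes) together with network-level statistics:
    Bayesian contrasts, between-network connectivity averages, hierarchy
    strength and hierarchical clustering of connectivity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
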