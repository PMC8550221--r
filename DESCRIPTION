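Package: soilc14
Title: Two-Pool Soil Carbon Dynamics Constrained by Bomb Radiocarbon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-steady-state two-pool series soil carbon model with a coupled
    radiocarbon tracer, for estimating decomposition and transfer rates from
    joint time series of topsoil carbon stocks and bulk Delta-14C spanning the
    atmospheric bomb spike. Provides conversion of pasture production records
    to carbon inputs, random-walk Metropolis MCMC parameter estimation with
    bootstrap confidence intervals and AIC model comparison, analytic transit
    time distributions, steady-state stock diagnostics, and a seeded
    synthetic-data generator for offline validation and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
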