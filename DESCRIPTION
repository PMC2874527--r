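Package: linlogmca
Title: Dynamic Linlog Modelling and Metabolic Control Analysis of Central
    Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Klaus", "Werner", email = "kwerner@example.org", role = c("aut", "cre"))
Description: Reconstruction, simulation and control analysis of a dynamic
    linear-logarithmic (linlog) kinetic model of the central carbon metabolism
    of HepG2 hepatoma cells.  The package ships a 49-reaction stoichiometric
    network (glycolysis, pentose-phosphate pathway, TCA cycle, cofactor
    turnover and transport) with 31 regulatory effects, detects conserved
    moieties and builds the reduced system, integrates the normalized mass
    balances for glucose-deprivation stimulus-response experiments with a
    stiff Rosenbrock solver, estimates scaled elasticities and reference
    concentrations from metabolite time series with a self-adaptive evolution
    strategy, and computes flux/concentration control coefficients, partial
    flux control coefficients, internal response coefficients and Jacobian
    stability.  A synthetic-data generator emulates the experimental design
    for download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
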