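Package: crnreduce
Title: Reduction of Biochemical Reaction Networks by Balanced Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-preserving reduction of biochemical reaction networks.
    Represents a network through its composition matrix Y, complex-graph
    incidence matrix A and stoichiometric matrix N = YA, identifies balanced
    complexes (complexes with zero net flux in every steady state of a
    constrained flux space) by paired linear programs, and removes them by
    graph rewiring that exactly preserves steady-state fluxes (arbitrary
    kinetics, single outgoing reaction) or steady-state concentration
    monomials (mass-action kinetics, any number of outgoing reactions).
    Includes constraint-based preprocessing (reversible-reaction splitting,
    blocked-reaction removal, flux balance and flux variability analysis),
    SBML and tabular input/output, validation checks for steady-state and
    conservation-law preservation, growth, flux-variability and essentiality
    comparisons, and synthetic network generators with independent oracles
    (vertex enumeration, mass-action ODE integration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    pracma,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
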