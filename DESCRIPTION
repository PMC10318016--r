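Package: hillswitch
Title: Hill-Function ODE Ensembles and Switching-System Combinatorics for
    Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dual description of gene-regulatory-network
    dynamics: RACIPE-style ensemble simulation of shifted-Hill ODE models
    over randomly sampled kinetic parameters, and the combinatorial
    decomposition of switching (Glass) system parameter space into domains
    with invariant state-transition-graph dynamics.  Provides the exact
    translation between the two parameterizations, state transition and
    Morse graphs with predicted attractor repertoires, event-driven and
    Euler integration of switching systems, closed-form basin-of-attraction
    separatrices for two-node motifs, and the comparison statistics
    (repertoire frequency distributions, Jensen-Shannon divergence,
    sampling-bias normalization, link strength, basin strength, PCA of
    parameter classes) that quantify the agreement between the two
    formalisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
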