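Package: thermolump
Title: Reaction Lumping and Thermodynamic Metabolic Flux Analysis for
    Models with Incomplete Gibbs Energy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies lumped reactions - nonnegative linear combinations of
    reactions whose standard Gibbs free energy change is undetermined - that
    eliminate metabolites lacking a standard Gibbs free energy of formation,
    so that thermodynamic constraints can be imposed on otherwise
    unconstrained parts of a genome-scale metabolic model.  Implements the
    group, sequential, naive-iterative and combined lumping procedures over
    the reduced stoichiometric submatrix, partitioning of unknown metabolites
    into independent groups via the bipartite metabolite-reaction graph, and
    thermodynamic metabolic flux analysis (TMFA) with lumped-reaction
    constraints, including Gibbs energy variability analysis and reaction
    reversibility classification.  Reads COBRA-style JSON and SBML L3/FBC
    models and tab-separated thermodynamic annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
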