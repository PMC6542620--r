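Package: TopoRewire
Title: Topological Reinforcement and Hebbian Rewiring for Modularity
    Emergence in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Adaptive rewiring rules that evolve random graphs toward
    modular, small-world architectures. Implements topological
    reinforcement (density-preserving insertion of links between
    non-neighbours with maximal topological overlap, plus uniform
    pruning), a Hebbian variant driven by functional connectivity from a
    three-state susceptible-excited-refractory (SER) excitable cellular
    automaton, and the consensus-clustering machinery (agreement
    matrices, size-preserving partition nulls, intramodule density,
    normalized mutual information) used to show that the final modules
    amplify "proto-modules" already present in the initial random graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
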