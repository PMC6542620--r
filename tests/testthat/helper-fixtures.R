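# small graphs built in code, shared across test files

pathGraph <- function(n = 3) igraph::make_ring(n, circular = FALSE)

twoCliques <- function(k = 5) {
  igraph::disjoint_union(igraph::make_full_graph(k), igraph::make_full_graph(k))
}

# circular lattice where each node links to its k/2 nearest neighbours per side
ringLattice <- function(n = 100, k = 4) {
  igraph::connect(igraph::make_ring(n), k / 2)
}

randomGraph <- function(n, p = 0.4) {
  igraph::sample_gnp(n, p, directed = FALSE)
}

# canonical sorted edge set for graph equality checks
canonEdges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}
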