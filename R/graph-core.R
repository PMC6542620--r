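#' Generate an Erdős–Rényi random graph with a fixed edge budget
#'
#' Draws a simple undirected G(n, M) graph with exactly
#' `M = round(lam * n / 2)` edges chosen uniformly among all node pairs, so
#' that the mean degree is `lam` and the density is `2M / (n (n - 1))`. The
#' fixed-edge-count flavour (rather than G(n, p)) is used so that density is
#' an exact invariant of the rewiring rules, which insert and prune equal
#' numbers of links.
#'
#' @param n number of nodes (>= 2).
#' @param lam target mean degree, `0 < lam <= n - 1`.
#' @param seed optional RNG seed.
#' @return an igraph object with `n` nodes and `round(lam * n / 2)` edges.
#' @examples
#' g <- generateER(100, 10, seed = 1)
#' igraph::ecount(g)        # 500
#' igraph::edge_density(g)  # ~0.1
#' @export
generateER <- function(n, lam, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("n must be >= 2")
  if (lam <= 0 || lam > n - 1)
    stop("lam must satisfy 0 < lam <= n - 1")
  m <- round(lam * n / 2)
  igraph::sample_gnm(n, m, directed = FALSE)
}

#' Topological overlap of all node pairs
#'
#' Neighbourhood similarity of node pairs, counting common neighbours and
#' normalizing by the smaller degree:
#' \deqn{to_{ij} = \frac{\sum_k a_{ik} a_{kj} + a_{ij}}
#'                      {\min(d_i, d_j) + 1 - a_{ij}}}
#' a close kin of the matching index. Entries lie in \[0, 1\]; the diagonal
#' is set to 0 and is never consulted by the rewiring rule. Isolated nodes
#' score 0 against every partner (the denominator reduces to 1).
#'
#' @param net an igraph object (simple, undirected).
#' @return a [ScoreMatrix-class] of kind `"TO"`.
#' @examples
#' path <- igraph::make_graph(~ a - b - c)
#' scoreValues(topologicalOverlap(path))[1, 3]  # 0.5
#' @export
topologicalOverlap <- function(net) {
  .assertNetwork(net)
  A <- .adjacency(net)
  deg <- rowSums(A)
  common <- A %*% A
  to <- (common + A) / (outer(deg, deg, pmin) + 1 - A)
  diag(to) <- 0
  ScoreMatrix(to, kind = "TO")
}

#' One stochastic Louvain community detection
#'
#' Runs the Louvain algorithm once (resolution 1) and returns the partition
#' together with its Newman–Girvan modularity Q. Louvain is stochastic via
#' its node ordering, and on weak-signal graphs repeated calls return
#' different, degenerate partitions; the consensus machinery
#' ([agreementMatrix()], [consensusPartitions()]) exploits exactly that.
#'
#' @param net an igraph object with at least one edge.
#' @param seed optional RNG seed (fixed seed gives a fixed partition).
#' @return list with elements `partition` (integer affiliation vector),
#'   `q` (modularity) and `nModules`.
#' @export
modularityLouvain <- function(net, seed = NULL) {
  .assertNetwork(net)
  if (igraph::ecount(net) < 1)
    stop("modularity is undefined on an edgeless graph")
  if (!is.null(seed)) set.seed(seed)
  cl <- igraph::cluster_louvain(net)
  memb <- as.integer(igraph::membership(cl))
  list(partition = memb,
       q = igraph::modularity(net, memb),
       nModules = length(unique(memb)))
}

#' Clustering, path length and small-world index
#'
#' Average local clustering coefficient, characteristic path length (on the
#' largest component if the graph is disconnected, flagged in the result)
#' and the small-world index \eqn{(C/C_{rand}) / (L/L_{rand})} computed
#' against `nNull` degree-preserving (Maslov–Sneppen) null graphs.
#'
#' @param net an igraph object.
#' @param nNull number of null graphs (>= 1).
#' @param seed optional RNG seed.
#' @return list with `clustering`, `pathLength`, `swIndex`, `connected`.
#' @export
smallWorldMetrics <- function(net, nNull = 10, seed = NULL) {
  .assertNetwork(net)
  if (nNull < 1) stop("nNull must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- igraph::components(net)
  connected <- comp$no == 1L
  g <- if (connected) net else
    igraph::induced_subgraph(net, which(comp$membership == which.max(comp$csize)))
  C <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(g)
  nulls <- lapply(seq_len(nNull), function(i) {
    gr <- maslovSneppenRewire(g)
    cr <- igraph::components(gr)
    if (cr$no > 1L)
      gr <- igraph::induced_subgraph(gr, which(cr$membership == which.max(cr$csize)))
    c(igraph::transitivity(gr, type = "localaverage", isolates = "zero"),
      igraph::mean_distance(gr))
  })
  nulls <- do.call(rbind, nulls)
  Cr <- mean(nulls[, 1]); Lr <- mean(nulls[, 2])
  list(clustering = C, pathLength = L,
       swIndex = (C / Cr) / (L / Lr), connected = connected)
}

#' Degree-preserving randomization (Maslov–Sneppen)
#'
#' Randomizes a graph by accepted double-edge swaps, one per link: two
#' distinct edges (a, b), (c, d) are replaced by (a, d), (c, b), rejecting
#' proposals that would create self-loops or multi-edges. The degree
#' sequence (and hence density) is exactly preserved. Swaps that cannot be
#' accepted within the retry budget are skipped with a message.
#'
#' @param net an igraph object with >= 2 edges.
#' @param seed optional RNG seed.
#' @param retriesPerSwap retry budget for each of the `|edges|` swaps.
#' @return a rewired igraph object with the same degree sequence.
#' @export
maslovSneppenRewire <- function(net, seed = NULL, retriesPerSwap = 100) {
  .assertNetwork(net)
  m <- igraph::ecount(net)
  if (m < 2) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  adj[el[, c(2, 1)]] <- TRUE
  skipped <- 0L
  for (s in seq_len(m)) {
    done <- FALSE
    for (try in seq_len(retriesPerSwap)) {
      ij <- sample.int(m, 2L)
      e1 <- el[ij[1L], ]; e2 <- el[ij[2L], ]
      if (stats::runif(1) < 0.5) e2 <- rev(e2)
      a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
      # propose (a,d) and (c,b)
      if (a == d || c == b || adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      el[ij[1L], ] <- c(a, d)
      el[ij[2L], ] <- c(c, b)
      done <- TRUE
      break
    }
    if (!done) skipped <- skipped + 1L
  }
  if (skipped > 0L)
    message("maslovSneppenRewire: ", skipped, " swap(s) skipped after retry budget")
  igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE), t(el))
}
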