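# insertion phase of one rewiring step: returns the unique unordered pairs
# to insert, all scored against the step-entry adjacency (simultaneous
# semantics). Eligible nodes have degree strictly between 0 and N-1.
.insertionPhase <- function(A, scores, batchSize) {
  n <- nrow(A)
  deg <- rowSums(A)
  eligible <- which(deg > 0 & deg < n - 1)
  if (length(eligible) == 0L)
    return(matrix(integer(0), nrow = 0, ncol = 2))
  batch <- if (length(eligible) <= batchSize) eligible
           else eligible[sample.int(length(eligible), batchSize)]
  pairs <- vapply(batch, function(u) {
    cand <- which(A[u, ] == 0)
    cand <- cand[cand != u]
    v <- cand[.whichMaxTie(scores[u, cand])]
    as.integer(c(min(u, v), max(u, v)))
  }, integer(2))
  unique(t(pairs))
}

#' One batch rewiring step driven by a score matrix
#'
#' The elementary move of both plasticity rules. (i) Sample `batchSize`
#' distinct eligible nodes (degree strictly between 0 and N-1) uniformly;
#' (ii) connect each sampled node u to the non-neighbour v maximizing
#' `scores[u, v]`, ties broken uniformly at random, with all insertions
#' evaluated against the step-entry adjacency (duplicate insertions
#' collapse to one edge); (iii) prune as many links as were actually
#' inserted, uniformly at random from the post-insertion edge set —
#' just-inserted links are themselves at risk. Density is therefore exactly
#' conserved. With no eligible node (e.g. a complete graph) the network is
#' returned unchanged with a warning.
#'
#' @param net an igraph object.
#' @param scores a [ScoreMatrix-class] (TO or FC) or plain symmetric matrix
#'   indexed like the nodes of `net`.
#' @param batchSize nodes rewired per step; default `floor(N/2)`.
#' @return the rewired igraph object (same edge count).
#' @seealso [runTopologicalReinforcement()], [runHebbian()]
#' @export
rewireStep <- function(net, scores, batchSize = NULL) {
  .assertNetwork(net)
  n <- igraph::vcount(net)
  v <- .scoreValues(scores, n)
  if (is.null(batchSize)) batchSize <- max(1L, floor(n / 2))
  if (batchSize < 1) stop("batchSize must be >= 1")
  A <- .adjacency(net)
  ins <- .insertionPhase(A, v, batchSize)
  if (nrow(ins) == 0L) {
    warning("no eligible node for rewiring; network unchanged")
    return(net)
  }
  g <- igraph::add_edges(net, t(ins))
  g <- igraph::delete_edges(g, sample.int(igraph::ecount(g), nrow(ins)))
  g
}

# one trajectory record: density, components, Q and module count averaged
# over nDetect Louvain runs (NA when nDetect = 0 or the graph is edgeless)
.trajRecord <- function(g, step, nDetect) {
  q_mean <- q_sd <- nm <- NA_real_
  if (nDetect > 0 && igraph::ecount(g) > 0) {
    runs <- vapply(seq_len(nDetect), function(i) {
      r <- modularityLouvain(g)
      c(r$q, r$nModules)
    }, numeric(2))
    q_mean <- mean(runs[1, ])
    q_sd <- if (nDetect > 1) stats::sd(runs[1, ]) else NA_real_
    nm <- mean(runs[2, ])
  }
  data.frame(step = step, q_mean = q_mean, q_sd = q_sd, n_modules_mean = nm,
             density = igraph::edge_density(g),
             n_components = igraph::components(g)$no)
}

#' Evolve a network by topological reinforcement
#'
#' Runs the topological-reinforcement (TR) rule for `r = round(lambda * K)`
#' steps, where `lambda = 2|E|/N` is the mean degree and `K` the average
#' number of rewirings per link. At each step the topological overlap is
#' recomputed from the current graph (once per step, not within the batch)
#' and one [rewireStep()] is applied, so about N links are reallocated per
#' step with `batchSize = floor(N/2)`. Per-step metrics are recorded;
#' disconnection events are recorded in `n_components`, not treated as
#' errors. `K = 3` keeps ER(100, 10) networks connected in practice.
#'
#' @param net initial igraph object.
#' @param K mean rewirings per link (default 3); `K = 0` returns the
#'   initial record only.
#' @param batchSize nodes rewired per step; default `floor(N/2)`.
#' @param nDetect Louvain detections per recorded step (0 skips Q tracking,
#'   which is much faster when only the final graph is needed).
#' @param seed optional RNG seed.
#' @param snapshotSteps integer steps at which to keep graph snapshots.
#' @return a [Trajectory-class] object.
#' @examples
#' g <- generateER(100, 10, seed = 1)
#' tr <- runTopologicalReinforcement(g, K = 3, nDetect = 3, seed = 2)
#' tr
#' @export
runTopologicalReinforcement <- function(net, K = 3, batchSize = NULL,
                                        nDetect = 5, seed = NULL,
                                        snapshotSteps = integer(0)) {
  .assertNetwork(net)
  if (K < 0) stop("K must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  if (is.null(batchSize)) batchSize <- max(1L, floor(n / 2))
  r <- as.integer(round(.meanDegree(net) * K))
  g <- net
  recs <- vector("list", r + 1L)
  recs[[1L]] <- .trajRecord(g, 0L, nDetect)
  snaps <- list()
  if (0L %in% snapshotSteps) snaps[["0"]] <- g
  for (t in seq_len(r)) {
    sc <- topologicalOverlap(g)
    g <- rewireStep(g, sc, batchSize)
    recs[[t + 1L]] <- .trajRecord(g, t, nDetect)
    if (t %in% snapshotSteps) snaps[[as.character(t)]] <- g
  }
  Trajectory(records = do.call(rbind, recs), graph = g,
             config = list(rule = "topological", K = K, steps = r,
                           batchSize = batchSize, nDetect = nDetect,
                           seed = seed),
             snapshots = snaps)
}
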