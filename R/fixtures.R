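#' Planted-partition (stochastic block) fixture graphs
#'
#' Generates a stochastic block model graph with the given within- and
#' between-block edge probabilities and returns it together with its
#' ground-truth partition. These graphs are the controlled stand-in for
#' "proto-modules": with `within` slightly above `between` they carry
#' exactly the kind of weak density fluctuations the rewiring rules
#' amplify, and the planted partition is the recovery oracle.
#'
#' @param n number of nodes.
#' @param nModules number of (near-)equal-sized blocks; every block must
#'   end up with at least 2 nodes.
#' @param within,between edge probabilities in \[0, 1\].
#' @param seed optional RNG seed.
#' @return list with `graph` (igraph) and `partition` (integer vector).
#' @export
generatePlantedPartition <- function(n, nModules, within, between,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(within, between) < 0) || any(c(within, between) > 1))
    stop("infeasible densities: within and between must lie in [0, 1]")
  sizes <- rep(n %/% nModules, nModules)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 2)) stop("every module must have at least 2 nodes")
  pref <- matrix(between, nModules, nModules)
  diag(pref) <- within
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  list(graph = g, partition = rep(seq_len(nModules), sizes))
}
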