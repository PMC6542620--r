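# internal helpers shared across modules

.assertNetwork <- function(net) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(net)) stop("`net` must be undirected", call. = FALSE)
  if (igraph::ecount(net) > 0 &&
      (any(igraph::which_loop(net)) || any(igraph::which_multiple(net))))
    stop("`net` must be simple (no self-loops or multi-edges)", call. = FALSE)
  invisible(net)
}

.adjacency <- function(net) {
  unname(as.matrix(igraph::as_adjacency_matrix(net, type = "both", sparse = FALSE)))
}

# argmax with uniform random tie-breaking
.whichMaxTie <- function(x) {
  m <- max(x)
  idx <- which(x >= m - 1e-12)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

# accept a ScoreMatrix or a plain symmetric matrix of the right size
.scoreValues <- function(scores, n) {
  v <- if (is(scores, "ScoreMatrix")) scores@values else as.matrix(scores)
  if (nrow(v) != n || ncol(v) != n)
    stop("score matrix must be ", n, " x ", n, call. = FALSE)
  v
}

.meanDegree <- function(net) 2 * igraph::ecount(net) / igraph::vcount(net)

# seeds for child runs, drawn from the current RNG stream
.childSeeds <- function(k) sample.int(.Machine$integer.max - 1L, k)
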