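#' Graph and matrix I/O
#'
#' Plain-text serialization used across the package: whitespace-delimited
#' edge lists with 0-based node ids (one pair per line), GraphML via
#' igraph, and headered CSV for score/agreement matrices.
#'
#' @param net an igraph object.
#' @param path file path.
#' @param nNodes node count for edge lists whose isolated tail nodes would
#'   otherwise be dropped (defaults to `max(id) + 1`).
#' @param m a matrix, [ScoreMatrix-class] or [AgreementMatrix-class].
#' @return readers return an igraph object or numeric matrix; writers
#'   return the path invisibly.
#' @name graph-io
NULL

#' @rdname graph-io
#' @export
writeEdgeList <- function(net, path) {
  .assertNetwork(net)
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname graph-io
#' @export
readEdgeList <- function(path, nNodes = NULL) {
  el <- utils::read.table(path)
  el <- as.matrix(el)
  storage.mode(el) <- "integer"
  if (any(el < 0)) stop("edge list node ids must be 0-based non-negative")
  n <- if (is.null(nNodes)) max(el) + 1L else as.integer(nNodes)
  igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                    t(el + 1L))
}

#' @rdname graph-io
#' @export
writeGraphML <- function(net, path) {
  .assertNetwork(net)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname graph-io
#' @export
readGraphML <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname graph-io
#' @export
writeMatrixCSV <- function(m, path) {
  v <- if (is(m, "ScoreMatrix")) scoreValues(m)
       else if (is(m, "AgreementMatrix")) agreementValues(m)
       else as.matrix(m)
  colnames(v) <- paste0("n", seq_len(ncol(v)) - 1L)
  utils::write.csv(v, path, row.names = FALSE)
  invisible(path)
}

#' @rdname graph-io
#' @export
readMatrixCSV <- function(path) {
  unname(as.matrix(utils::read.csv(path)))
}
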