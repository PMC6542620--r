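#' @import methods
NULL

.isSymmetricNum <- function(m, tol = 1e-8) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol
}

#' Pairwise score matrix driving link insertion
#'
#' A symmetric N x N matrix of pairwise node scores in \[0, 1\] with a zero
#' diagonal, tagged by the quantity it holds: topological overlap (`"TO"`)
#' or SER functional connectivity (`"FC"`). Score matrices are what the
#' rewiring engine ranks non-neighbour candidates by; the diagonal is never
#' consulted.
#'
#' @slot values symmetric numeric matrix, entries in \[0, 1\], zero diagonal.
#' @slot kind one of `"TO"`, `"FC"`.
#'
#' @seealso [topologicalOverlap()], [normalizeFC()], [rewireStep()]
#' @export
setClass("ScoreMatrix",
  representation(values = "matrix", kind = "character"),
  validity = function(object) {
    v <- object@values
    if (!.isSymmetricNum(v)) return("values must be a symmetric numeric matrix")
    if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("entries must lie in [0, 1]")
    if (any(diag(v) != 0)) return("diagonal must be zero")
    if (length(object@kind) != 1L || !object@kind %in% c("TO", "FC"))
      return("kind must be \"TO\" or \"FC\"")
    TRUE
  }
)

#' @rdname ScoreMatrix-class
#' @param values symmetric numeric matrix.
#' @param kind score tag, `"TO"` or `"FC"`.
#' @return a `ScoreMatrix` object.
#' @export
ScoreMatrix <- function(values, kind = c("TO", "FC")) {
  kind <- match.arg(kind)
  new("ScoreMatrix", values = unname(as.matrix(values)), kind = kind)
}

#' Co-classification frequencies across a set of partitions
#'
#' Agreement (consensus) matrix: entry (i, j) is the relative frequency with
#' which nodes i and j were assigned to the same module across a collection
#' of partitions. Symmetric, unit diagonal, entries in \[0, 1\]. Instances
#' are the P, P_init and P_null matrices of the proto-module analysis.
#'
#' @slot values symmetric numeric matrix with unit diagonal.
#' @slot nPartitions number of partitions the matrix was built from.
#'
#' @seealso [agreementMatrix()], [nullAgreement()], [consensusPartitions()]
#' @export
setClass("AgreementMatrix",
  representation(values = "matrix", nPartitions = "integer"),
  validity = function(object) {
    v <- object@values
    if (!.isSymmetricNum(v)) return("values must be a symmetric numeric matrix")
    if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("entries must lie in [0, 1]")
    if (any(abs(diag(v) - 1) > 1e-12)) return("diagonal must be 1")
    if (object@nPartitions < 1L) return("nPartitions must be >= 1")
    TRUE
  }
)

#' @rdname AgreementMatrix-class
#' @param values symmetric numeric matrix with unit diagonal.
#' @param nPartitions count of partitions used.
#' @return an `AgreementMatrix` object.
#' @export
AgreementMatrix <- function(values, nPartitions) {
  new("AgreementMatrix", values = unname(as.matrix(values)),
      nPartitions = as.integer(nPartitions))
}

#' Transition probabilities of the SER excitable model
#'
#' The stochastic knobs of the susceptible-excited-refractory automaton:
#' `f`, the probability that a susceptible node fires spontaneously (without
#' an excited neighbour), and `p`, the probability that a refractory node
#' recovers to susceptible. The deterministic regime is `f = 0, p = 1`,
#' where the only randomness left is in the initial condition.
#'
#' @slot f spontaneous-activation probability in \[0, 1\].
#' @slot p recovery probability in (0, 1\].
#'
#' @seealso [serStep()], [simulateStochasticFC()]
#' @export
setClass("SERParams",
  representation(f = "numeric", p = "numeric"),
  validity = function(object) {
    if (length(object@f) != 1L || object@f < 0 || object@f > 1)
      return("f must be a single value in [0, 1]")
    if (length(object@p) != 1L || object@p <= 0 || object@p > 1)
      return("p must be a single value in (0, 1]")
    TRUE
  }
)

#' @rdname SERParams-class
#' @param f spontaneous-activation probability.
#' @param p recovery probability.
#' @return a `SERParams` object.
#' @export
SERParams <- function(f = 0, p = 1) new("SERParams", f = f, p = p)

#' Record of an adaptive-rewiring run
#'
#' Per-step metrics of a topological-reinforcement or Hebbian run (steps
#' t = 0..r): modularity Q averaged over repeated Louvain detections, mean
#' module count, density and connected-component count, plus the final
#' graph, the run configuration and any requested intermediate snapshots.
#' Density is constant across all records by construction of the rule.
#'
#' @slot records data.frame with columns `step`, `q_mean`, `q_sd`,
#'   `n_modules_mean`, `density`, `n_components`.
#' @slot graph final igraph object.
#' @slot config list of run parameters (rule, K, steps, batchSize, ...).
#' @slot snapshots named list of igraph snapshots keyed by step.
#'
#' @seealso [runTopologicalReinforcement()], [runHebbian()]
#' @export
setClass("Trajectory",
  representation(records = "data.frame", graph = "ANY",
                 config = "list", snapshots = "list"),
  validity = function(object) {
    need <- c("step", "q_mean", "q_sd", "n_modules_mean", "density",
              "n_components")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    TRUE
  }
)

Trajectory <- function(records, graph, config = list(), snapshots = list()) {
  new("Trajectory", records = records, graph = graph, config = config,
      snapshots = snapshots)
}

#' Results of the proto-module analysis pipeline
#'
#' Holds the agreement matrices (final-run P and initial-graph P_init),
#' their consensus partitions, summary statistics with empirical p-values,
#' and the underlying distributions (agreement values, intramodule
#' densities, null draws) as tidy tables.
#'
#' @slot stats named list of scalar statistics and empirical p-values.
#' @slot tables named list of data.frames (value distributions, null draws).
#' @slot P final-partition agreement matrix.
#' @slot Pinit initial-graph agreement matrix.
#' @slot consensusP list of consensus partitions of P.
#' @slot consensusPinit list of consensus partitions of P_init.
#' @slot flags character vector of degeneracy/partial-failure flags.
#'
#' @seealso [protoModuleAnalysis()]
#' @export
setClass("ProtoModuleReport",
  representation(stats = "list", tables = "list", P = "AgreementMatrix",
                 Pinit = "AgreementMatrix", consensusP = "list",
                 consensusPinit = "list", flags = "character")
)
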