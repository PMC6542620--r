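#' Agreement matrix across partitions
#'
#' Co-classification frequency of every node pair: entry (i, j) is the
#' fraction of partitions in which i and j carry the same module label.
#'
#' @param partitions list of affiliation vectors of equal length.
#' @return an [AgreementMatrix-class].
#' @examples
#' agreementValues(agreementMatrix(list(c(0, 0, 1), c(0, 1, 1))))
#' @export
agreementMatrix <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 1)
    stop("need at least one partition")
  n <- length(partitions[[1L]])
  P <- matrix(0, n, n)
  for (p in partitions) {
    if (length(p) != n) stop("all partitions must have length ", n)
    P <- P + outer(p, p, "==")
  }
  AgreementMatrix(P / length(partitions), nPartitions = length(partitions))
}

#' Consensus partitions of an agreement matrix
#'
#' Treats the agreement matrix (diagonal zeroed) as a weighted graph and
#' applies weighted Louvain `n` times, returning a representative set of
#' consensus partitions. A single round of detect-agree-detect is used; the
#' procedure is not iterated to a fixed point.
#'
#' @param P an [AgreementMatrix-class].
#' @param n number of detections (default 100).
#' @param seed optional RNG seed.
#' @return list of integer affiliation vectors.
#' @export
consensusPartitions <- function(P, n = 100, seed = NULL) {
  if (!is(P, "AgreementMatrix")) stop("P must be an AgreementMatrix")
  if (!is.null(seed)) set.seed(seed)
  W <- agreementValues(P)
  diag(W) <- 0
  if (all(W == 0)) stop("agreement matrix has no off-diagonal support")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lapply(seq_len(n), function(i)
    as.integer(igraph::membership(igraph::cluster_louvain(g))))
}

#' Consensus clustering of the initial graph
#'
#' Applies Louvain `nDetect` times to the graph, builds the agreement
#' matrix P_init, then extracts `nConsensus` consensus partitions from
#' P_init. This is how stable "proto-module" partitions are read out of a
#' weak-signal random graph despite the degeneracy of single Louvain runs.
#'
#' @param net an igraph object.
#' @param nDetect Louvain runs on the graph (default 500).
#' @param nConsensus detections on P_init (default 100).
#' @param seed optional RNG seed.
#' @return list with `P` (the [AgreementMatrix-class] P_init), `partitions`
#'   (consensus partitions of P_init) and `detections` (the raw graph
#'   partitions).
#' @export
initialAgreement <- function(net, nDetect = 500, nConsensus = 100,
                             seed = NULL) {
  .assertNetwork(net)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(nDetect), function(i) modularityLouvain(net)$partition)
  P <- agreementMatrix(parts)
  list(P = P, partitions = consensusPartitions(P, nConsensus),
       detections = parts)
}

#' Partition overlap (normalized mutual information)
#'
#' NMI between two affiliation vectors with arithmetic-mean normalization
#' (2 I / (H1 + H2)), in \[0, 1\]. Degenerate cases follow fixed
#' conventions so that sweeps never divide 0 by 0: two single-module
#' partitions give 1, a single-module partition against a non-trivial one
#' gives 0; both carry attribute `degenerate = TRUE` so downstream
#' statistics can exclude them.
#'
#' @param p1,p2 affiliation vectors of equal length.
#' @return NMI in \[0, 1\] (possibly flagged).
#' @export
partitionOverlap <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions must have equal length")
  k1 <- length(unique(p1))
  k2 <- length(unique(p2))
  if (k1 == 1L && k2 == 1L) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (k1 == 1L || k2 == 1L) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  igraph::compare(as.integer(factor(p1)), as.integer(factor(p2)),
                  method = "nmi")
}

#' Pearson similarity between symmetric matrices
#'
#' Correlation over the upper-triangle off-diagonal entries; used to
#' compare adjacency matrices and agreement matrices alike. Returns `NA`
#' with attribute `degenerate = TRUE` when either triangle is constant.
#'
#' @param m1,m2 symmetric matrices of equal dimension.
#' @return Pearson correlation (possibly flagged `NA`).
#' @export
matrixSimilarity <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have equal dimensions")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}

#' Size-preserving partition null (P_null)
#'
#' Shuffles each partition's affiliation vector uniformly at random —
#' preserving the number of modules and their sizes while destroying the
#' node identities — and computes the agreement across the shuffled
#' partitions. This is the chance level of agreement for the given module
#' size structure; its expected off-diagonal value is
#' \eqn{\sum_m s_m (s_m - 1) / (N (N - 1))}.
#'
#' @param partitions list of affiliation vectors.
#' @param seed optional RNG seed.
#' @return an [AgreementMatrix-class].
#' @export
nullAgreement <- function(partitions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agreementMatrix(lapply(partitions, sample))
}

#' Mean intramodule density
#'
#' For each module with at least two nodes, the density of the subgraph it
#' induces (within-module edges over within-module pairs); returns the
#' unweighted mean across such modules. Singleton modules are excluded; if
#' every module is a singleton the quantity is undefined and an error is
#' raised. Under size-preserving shuffled partitions of an ER graph this
#' centres on the graph density.
#'
#' @param net an igraph object.
#' @param part affiliation vector on the nodes of `net`.
#' @return mean within-module density.
#' @export
intramoduleDensity <- function(net, part) {
  .assertNetwork(net)
  n <- igraph::vcount(net)
  if (length(part) != n) stop("partition must have length ", n)
  A <- .adjacency(net)
  dens <- numeric(0)
  for (lab in unique(part)) {
    idx <- which(part == lab)
    s <- length(idx)
    if (s < 2) next
    dens <- c(dens, sum(A[idx, idx]) / (s * (s - 1)))
  }
  if (!length(dens))
    stop("all modules are singletons; intramodule density undefined")
  mean(dens)
}

# mean pairwise NMI between two sets of partitions, capped at maxPairs
# uniformly sampled pairs to bound the cost of null draws
.meanPairNMI <- function(set1, set2, maxPairs = 2000) {
  grid <- expand.grid(i = seq_along(set1), j = seq_along(set2))
  if (nrow(grid) > maxPairs)
    grid <- grid[sample.int(nrow(grid), maxPairs), ]
  mean(vapply(seq_len(nrow(grid)), function(k)
    as.numeric(partitionOverlap(set1[[grid$i[k]]], set2[[grid$j[k]]])),
    numeric(1)))
}

#' Proto-module analysis of an initial graph
#'
#' The full pipeline probing whether the modules of rewired networks
#' amplify "proto-modules" (chance density fluctuations) of the initial
#' graph:
#' \enumerate{
#'   \item `nRuns` rewiring runs from the same initial graph; one Louvain
#'     partition per final graph; agreement matrix P and its consensus
#'     partitions.
#'   \item Consensus clustering of the initial graph itself (P_init and its
#'     consensus partitions) via [initialAgreement()].
#'   \item (a) Pearson similarity and partition overlap between the initial
#'     and each final network, against degree-preserving rewired nulls;
#'     (b) the value distributions of P vs the size-preserving null P_null,
#'     and intramodule-density distributions of the initial graph under
#'     consensus-of-P partitions, direct graph partitions, and shuffled
#'     null partitions (plus the final-graph reference); (c) similarity of
#'     P_init and P, and mean all-pairs overlap between their consensus
#'     partition sets, each against its null distribution.
#' }
#' Empirical p-values use the (b + 1) / (n + 1) convention.
#'
#' @param net initial igraph object.
#' @param nRuns rewiring runs (default 500).
#' @param nDetectInit Louvain runs on the initial graph (default 500).
#' @param nConsensus consensus detections on P and P_init (default 100).
#' @param nNull null draws for each empirical p-value (default 100).
#' @param nDensity repetitions of each intramodule-density family
#'   (default 500).
#' @param K mean rewirings per link for the default TR runner.
#' @param seed optional RNG seed.
#' @param rewireFun optional function(graph) -> final graph replacing the
#'   default topological-reinforcement runner (e.g. a Hebbian runner).
#' @param maxNullPairs cap on partition pairs per overlap evaluation.
#' @return a [ProtoModuleReport-class].
#' @export
protoModuleAnalysis <- function(net, nRuns = 500, nDetectInit = 500,
                                nConsensus = 100, nNull = 100, nDensity = 500,
                                K = 3, seed = NULL, rewireFun = NULL,
                                maxNullPairs = 2000) {
  .assertNetwork(net)
  if (nRuns < 1) stop("nRuns must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  flags <- character(0)
  if (is.null(rewireFun))
    rewireFun <- function(g) finalGraph(runTopologicalReinforcement(g, K = K,
                                                                    nDetect = 0))
  finals <- lapply(seq_len(nRuns), function(i) rewireFun(net))
  finalParts <- lapply(finals, function(g) modularityLouvain(g)$partition)
  P <- agreementMatrix(finalParts)
  consP <- consensusPartitions(P, nConsensus)
  ia <- initialAgreement(net, nDetect = nDetectInit, nConsensus = nConsensus)
  Pinit <- ia$P
  consPinit <- ia$partitions
  initParts <- ia$detections
  A0 <- .adjacency(net)

  # (a) initial vs final networks, against degree-preserving nulls
  sims <- vapply(finals, function(g)
    as.numeric(matrixSimilarity(A0, .adjacency(g))), numeric(1))
  nmis <- vapply(seq_len(nRuns), function(i)
    as.numeric(partitionOverlap(initParts[[(i - 1L) %% nDetectInit + 1L]],
                                finalParts[[i]])), numeric(1))
  simsNull <- vapply(seq_len(nNull), function(i) {
    gg <- maslovSneppenRewire(net)
    as.numeric(matrixSimilarity(.adjacency(gg),
                                .adjacency(finals[[(i - 1L) %% nRuns + 1L]])))
  }, numeric(1))
  nmisNull <- vapply(seq_len(nNull), function(i) {
    gg <- maslovSneppenRewire(net)
    as.numeric(partitionOverlap(modularityLouvain(gg)$partition,
                                finalParts[[(i - 1L) %% nRuns + 1L]]))
  }, numeric(1))
  pSim <- (sum(simsNull >= mean(sims)) + 1) / (nNull + 1)
  pNmi <- (sum(nmisNull >= mean(nmis)) + 1) / (nNull + 1)

  # (b) P values vs P_null; intramodule-density distributions
  Pnull <- nullAgreement(finalParts)
  densCons <- vapply(seq_len(nDensity), function(i)
    intramoduleDensity(net, consP[[(i - 1L) %% length(consP) + 1L]]),
    numeric(1))
  densGraph <- vapply(seq_len(nDensity), function(i)
    intramoduleDensity(net, modularityLouvain(net)$partition), numeric(1))
  densNull <- vapply(seq_len(nDensity), function(i)
    intramoduleDensity(net, sample(initParts[[(i - 1L) %% nDetectInit + 1L]])),
    numeric(1))
  densFinal <- vapply(seq_len(nRuns), function(i)
    intramoduleDensity(finals[[i]], finalParts[[i]]), numeric(1))

  # (c) P_init vs P
  simPP <- as.numeric(matrixSimilarity(agreementValues(Pinit),
                                       agreementValues(P)))
  simPPnull <- vapply(seq_len(nNull), function(i)
    as.numeric(matrixSimilarity(agreementValues(Pinit),
                                agreementValues(nullAgreement(finalParts)))),
    numeric(1))
  pSimPP <- (sum(simPPnull >= simPP) + 1) / (nNull + 1)
  nmiObs <- .meanPairNMI(consPinit, consP, maxPairs = maxNullPairs)
  nmiNull <- vapply(seq_len(nNull), function(i)
    .meanPairNMI(consPinit, lapply(consP, sample), maxPairs = maxNullPairs),
    numeric(1))
  pNmiPP <- (sum(nmiNull >= nmiObs) + 1) / (nNull + 1)

  if (nRuns < 2)
    flags <- c(flags, "degenerate agreement: P built from a single partition")

  ut <- upper.tri(agreementValues(P))
  new("ProtoModuleReport",
      stats = list(
        similarity_init_final = mean(sims), p_similarity_init_final = pSim,
        nmi_init_final = mean(nmis), p_nmi_init_final = pNmi,
        similarity_Pinit_P = simPP, p_similarity_Pinit_P = pSimPP,
        similarity_Pinit_P_null95 = unname(stats::quantile(simPPnull, 0.95)),
        nmi_consensus = nmiObs, p_nmi_consensus = pNmiPP,
        nmi_consensus_null95 = unname(stats::quantile(nmiNull, 0.95)),
        intramodule_density_consensus = mean(densCons),
        intramodule_density_graph = mean(densGraph),
        intramodule_density_null = mean(densNull),
        intramodule_density_final = mean(densFinal)),
      tables = list(
        init_final = data.frame(similarity = sims, nmi = nmis),
        init_final_null = data.frame(similarity = simsNull, nmi = nmisNull),
        agreement_values = data.frame(P = agreementValues(P)[ut],
                                      P_null = agreementValues(Pnull)[ut]),
        intramodule_density = data.frame(
          family = rep(c("consensus", "graph", "null"), each = nDensity),
          density = c(densCons, densGraph, densNull)),
        intramodule_density_final = data.frame(density = densFinal),
        Pinit_P_null = data.frame(similarity = simPPnull, nmi = nmiNull)),
      P = P, Pinit = Pinit, consensusP = consP, consensusPinit = consPinit,
      flags = flags)
}
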