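#' Evolve a network by the Hebbian (FC-driven) rule
#'
#' The activity-based counterpart of [runTopologicalReinforcement()]: the
#' same batch rewiring engine, with functional connectivity from the SER
#' model substituted for topological overlap as the insertion score. At
#' each of the `r = round(lambda * K)` steps, FC is re-estimated from
#' scratch on the current graph over the configured activity window
#' (deterministic protocol: `windowRuns` runs of `windowSteps` updates;
#' stochastic protocol: one run of `stochSteps` updates), then one
#' [rewireStep()] is applied. If the estimated FC is all zero (dead
#' dynamics) a warning is emitted and the step inserts uniformly at random
#' among non-neighbours, keeping the density bookkeeping intact. The total
#' number of rewiring steps matches a TR run with the same `K`, so the two
#' modalities are directly comparable.
#'
#' @param net initial igraph object.
#' @param params a [SERParams-class] object; `f = 0, p = 1` selects the
#'   deterministic protocol.
#' @param K mean rewirings per link (default 3).
#' @param batchSize nodes rewired per step; default `floor(N/2)`.
#' @param nDetect Louvain detections per recorded step (0 to skip).
#' @param windowRuns,windowSteps deterministic-protocol window (defaults
#'   500 x 30, a desk-scale version of the full 5000 x 30 protocol).
#' @param stochSteps stochastic-protocol window (default 5000; the full
#'   protocol uses 50000).
#' @param proportions optional fixed (e, s, r) initial proportions for the
#'   deterministic protocol.
#' @param seed optional RNG seed.
#' @param snapshotSteps integer steps at which to keep graph snapshots.
#' @return a [Trajectory-class] object.
#' @export
runHebbian <- function(net, params = SERParams(), K = 3, batchSize = NULL,
                       nDetect = 5, windowRuns = 500, windowSteps = 30,
                       stochSteps = 5000, proportions = NULL, seed = NULL,
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
    fc <- if (isDeterministic(params)) {
      simulateDeterministicFC(g, nRuns = windowRuns, tSteps = windowSteps,
                              proportions = proportions)
    } else {
      simulateStochasticFC(g, params, tSteps = stochSteps)
    }
    v <- scoreValues(fc)
    if (all(v == 0)) {
      warning("all-zero functional connectivity at step ", t,
              "; inserting uniformly at random")
      v[] <- 1
      diag(v) <- 0
    }
    g <- rewireStep(g, v, batchSize)
    recs[[t + 1L]] <- .trajRecord(g, t, nDetect)
    if (t %in% snapshotSteps) snaps[[as.character(t)]] <- g
  }
  Trajectory(records = do.call(rbind, recs), graph = g,
             config = list(rule = "hebbian", K = K, steps = r,
                           batchSize = batchSize, nDetect = nDetect,
                           f = params@f, p = params@p,
                           windowRuns = windowRuns, windowSteps = windowSteps,
                           stochSteps = stochSteps, seed = seed),
             snapshots = snaps)
}

#' Correlation between topological overlap and functional connectivity
#'
#' Pearson correlation between the upper-triangle off-diagonal entries of
#' the TO matrix of `net` and a given FC matrix. A sufficiently positive
#' TO-FC correlation in the initial configuration is the condition under
#' which the Hebbian rule acts as topological reinforcement and modularity
#' emerges. When either vector is constant the correlation is undefined and
#' `NA` is returned with attribute `degenerate = TRUE`.
#'
#' @param net an igraph object.
#' @param fc a [ScoreMatrix-class] (or symmetric matrix) computed on `net`.
#' @return a correlation in \[-1, 1\], or flagged `NA`.
#' @export
toFcCorrelation <- function(net, fc) {
  .assertNetwork(net)
  n <- igraph::vcount(net)
  to <- scoreValues(topologicalOverlap(net))
  f <- .scoreValues(fc, n)
  ut <- upper.tri(to)
  x <- to[ut]; y <- f[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}

#' Sweep SER settings: TO-FC correlation vs modularity gain
#'
#' For each SER setting in `grid`, measures the initial-graph TO-FC
#' correlation and the modularity gain `delta_q` of the Hebbian rule
#' (mean final Q over `nRuns` runs minus initial Q, both averaged over
#' `nDetect` Louvain detections). Per-setting failures are logged with a
#' message and reported as `NA` rows; the sweep continues.
#'
#' @param net initial igraph object.
#' @param grid data.frame of settings with columns `regime`
#'   ("deterministic" or "stochastic"), `f`, `p` (stochastic rows) and
#'   `e`, `s`, `r` (deterministic rows; `NA` where unused).
#' @param nRuns Hebbian runs per setting (the full protocol uses 150).
#' @param K mean rewirings per link.
#' @param nDetect Louvain detections for each Q estimate.
#' @param windowRuns,windowSteps,stochSteps activity windows, as in
#'   [runHebbian()].
#' @param seed optional RNG seed.
#' @return a data.frame: the grid plus `to_fc_corr` and `delta_q`.
#' @export
parameterSweep <- function(net, grid, nRuns = 150, K = 3, nDetect = 5,
                           windowRuns = 500, windowSteps = 30,
                           stochSteps = 5000, seed = NULL) {
  .assertNetwork(net)
  if (!is.data.frame(grid) || nrow(grid) < 1 || !"regime" %in% names(grid))
    stop("grid must be a data.frame with a `regime` column")
  if (!is.null(seed)) set.seed(seed)
  q0 <- mean(vapply(seq_len(nDetect), function(i) modularityLouvain(net)$q,
                    numeric(1)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, , drop = FALSE]
    out <- cell
    out$to_fc_corr <- NA_real_
    out$delta_q <- NA_real_
    tryCatch({
      det <- identical(cell$regime, "deterministic")
      if (det) {
        prop <- c(cell$e, cell$s, cell$r)
        fc0 <- simulateDeterministicFC(net, nRuns = windowRuns,
                                       tSteps = windowSteps,
                                       proportions = prop)
        pars <- SERParams(0, 1)
      } else {
        pars <- SERParams(cell$f, cell$p)
        fc0 <- simulateStochasticFC(net, pars, tSteps = stochSteps)
      }
      out$to_fc_corr <- as.numeric(toFcCorrelation(net, fc0))
      finalQ <- vapply(seq_len(nRuns), function(j) {
        tr <- runHebbian(net, pars, K = K, nDetect = 0,
                         windowRuns = windowRuns, windowSteps = windowSteps,
                         stochSteps = stochSteps,
                         proportions = if (det) c(cell$e, cell$s, cell$r))
        mean(vapply(seq_len(nDetect),
                    function(k) modularityLouvain(finalGraph(tr))$q,
                    numeric(1)))
      }, numeric(1))
      out$delta_q <- mean(finalQ) - q0
      out
    }, error = function(e) {
      message("parameterSweep: setting ", i, " failed: ", conditionMessage(e))
      out
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
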