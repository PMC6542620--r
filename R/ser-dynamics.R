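# SER states are encoded as integers: 0 = susceptible, 1 = excited,
# 2 = refractory.

# synchronous SER update on a column-batch of states (N x nRuns), all
# transitions evaluated against the input state
.serStepMatrix <- function(A, states, f, p) {
  excited <- states == 1L
  sus <- states == 0L
  ref <- states == 2L
  drive <- (A %*% excited) > 0
  out <- states
  out[excited] <- 2L
  if (f > 0) {
    fire <- drive | matrix(stats::runif(length(states)) < f,
                           nrow(states), ncol(states))
  } else fire <- drive
  out[sus] <- ifelse(fire[sus], 1L, 0L)
  if (p < 1) {
    rec <- matrix(stats::runif(length(states)) < p, nrow(states), ncol(states))
    out[ref] <- ifelse(rec[ref], 0L, 2L)
  } else out[ref] <- 0L
  out
}

# draw (nE, nS, nR) uniformly among all integer compositions of n into 3
# parts, i.e. uniformly over the full space of achievable state proportions
.sampleComposition <- function(n) {
  k <- sample.int(((n + 1L) * (n + 2L)) %/% 2L, 1L)
  i <- 0L
  while (k > n - i + 1L) {
    k <- k - (n - i + 1L)
    i <- i + 1L
  }
  c(i, k - 1L, n - i - (k - 1L))  # (E, S, R)
}

# counts from target proportions (e, s, r) by largest remainder
.proportionCounts <- function(n, prop) {
  if (length(prop) != 3L || any(prop < 0) || sum(prop) <= 0)
    stop("proportions must be three non-negative values")
  raw <- prop / sum(prop) * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

# state vector with given (E, S, R) counts assigned by uniform permutation
.randomState <- function(counts) {
  sample(rep.int(c(1L, 0L, 2L), counts))
}

#' One synchronous update of the SER automaton
#'
#' Applies the susceptible-excited-refractory transition rules once, all
#' against the input state: S becomes E if at least one neighbour is
#' excited, otherwise spontaneously with probability `f`; E always becomes
#' R; R recovers to S with probability `p`.
#'
#' @param net an igraph object.
#' @param state integer vector of states (0 = S, 1 = E, 2 = R), length N.
#' @param params a [SERParams-class] object.
#' @return the updated integer state vector.
#' @examples
#' tri <- igraph::make_ring(3)
#' serStep(tri, c(1L, 0L, 0L), SERParams(0, 1))  # c(2, 1, 1): (R, E, E)
#' @export
serStep <- function(net, state, params = SERParams()) {
  .assertNetwork(net)
  n <- igraph::vcount(net)
  if (length(state) != n) stop("state must have length ", n)
  if (!all(state %in% 0:2)) stop("states must be 0 (S), 1 (E) or 2 (R)")
  .serStepMatrix(.adjacency(net), matrix(as.integer(state), ncol = 1),
                 params@f, params@p)[, 1L]
}

#' Simulate an SER history
#'
#' Runs the automaton for `tSteps` synchronous updates and returns the full
#' state history including the initial state at t = 0.
#'
#' @param net an igraph object.
#' @param init integer initial state vector (0/1/2).
#' @param tSteps number of updates.
#' @param params a [SERParams-class] object.
#' @param seed optional RNG seed.
#' @return integer matrix of dim `(tSteps + 1) x N`.
#' @export
simulateSER <- function(net, init, tSteps, params = SERParams(), seed = NULL) {
  .assertNetwork(net)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  if (length(init) != n) stop("init must have length ", n)
  A <- .adjacency(net)
  H <- matrix(NA_integer_, tSteps + 1L, n)
  H[1L, ] <- as.integer(init)
  st <- matrix(as.integer(init), ncol = 1)
  for (t in seq_len(tSteps)) {
    st <- .serStepMatrix(A, st, params@f, params@p)
    H[t + 1L, ] <- st[, 1L]
  }
  H
}

#' Co-activation counts from an SER history
#'
#' Counts joint excitations over all recorded time points (t = 0 included):
#' \eqn{c_{ij} = \sum_t 1_E(x_i^t) 1_E(x_j^t)}. The diagonal holds each
#' node's excitation count, so \eqn{c_{ij} \le \min(c_{ii}, c_{jj})}.
#'
#' @param hist integer state-history matrix (time x nodes), as returned by
#'   [simulateSER()].
#' @return symmetric numeric matrix of co-activation counts.
#' @export
coactivation <- function(hist) {
  if (!is.matrix(hist) || nrow(hist) < 1)
    stop("hist must be a non-empty time x nodes matrix")
  E <- (hist == 1L) + 0
  crossprod(E)
}

#' Normalize co-activations into functional connectivity
#'
#' Scales co-activation counts into \[0, 1\]:
#' \eqn{fc_{ij} = c_{ij} / \min(c_{ii}, c_{jj})}, with the convention
#' `fc = 0` when the smaller excitation count is zero (a never-excited node
#' carries no co-activation evidence and must not attract links). The
#' diagonal is set to 0 for rewiring use.
#'
#' @param c symmetric co-activation matrix (diagonal = excitation counts).
#' @return a [ScoreMatrix-class] of kind `"FC"`.
#' @export
normalizeFC <- function(c) {
  cm <- as.matrix(c)
  d <- diag(cm)
  mn <- outer(d, d, pmin)
  fc <- ifelse(mn > 0, cm / mn, 0)
  diag(fc) <- 0
  ScoreMatrix(fc, kind = "FC")
}

#' Functional connectivity under the deterministic SER protocol
#'
#' Estimates FC in the deterministic regime (f = 0, p = 1) from many short
#' runs: for each run an initial composition (nE, nS, nR) is drawn
#' uniformly over all compositions of N (covering the full space of state
#' proportions) — or held at `proportions` if given — states are assigned
#' by uniform random permutation, and the automaton is run for `tSteps`
#' updates. Co-activation counts are accumulated over all time points
#' (t = 0 included) and averaged over runs, then normalized once on the
#' averaged counts (per-run normalization, which is unstable for runs with
#' never-excited nodes, is available via `perRunNormalize`).
#'
#' @param net an igraph object.
#' @param nRuns number of independent runs (default 5000).
#' @param tSteps updates per run (default 30).
#' @param proportions optional fixed (e, s, r) proportions for every run.
#' @param seed optional RNG seed.
#' @param perRunNormalize normalize each run before averaging instead.
#' @param raw return the run-averaged co-activation count matrix instead of
#'   the normalized [ScoreMatrix-class].
#' @return a [ScoreMatrix-class] of kind `"FC"` (or a matrix if `raw`).
#' @export
simulateDeterministicFC <- function(net, nRuns = 5000, tSteps = 30,
                                    proportions = NULL, seed = NULL,
                                    perRunNormalize = FALSE, raw = FALSE) {
  .assertNetwork(net)
  if (nRuns < 1 || tSteps < 1) stop("nRuns and tSteps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  A <- .adjacency(net)
  n <- nrow(A)
  states <- vapply(seq_len(nRuns), function(i) {
    cnt <- if (is.null(proportions)) .sampleComposition(n)
           else .proportionCounts(n, proportions)
    .randomState(cnt)
  }, integer(n))
  if (perRunNormalize) {
    Fsum <- matrix(0, n, n)
    for (run in seq_len(nRuns)) {
      H <- matrix(FALSE, tSteps + 1L, n)
      st <- states[, run, drop = FALSE]
      H[1L, ] <- st[, 1L] == 1L
      for (t in seq_len(tSteps)) {
        st <- .serStepMatrix(A, st, 0, 1)
        H[t + 1L, ] <- st[, 1L] == 1L
      }
      Fsum <- Fsum + scoreValues(normalizeFC(crossprod(H + 0)))
    }
    return(ScoreMatrix(Fsum / nRuns, kind = "FC"))
  }
  E <- (states == 1L) + 0
  C <- tcrossprod(E)
  for (t in seq_len(tSteps)) {
    states <- .serStepMatrix(A, states, 0, 1)
    E <- (states == 1L) + 0
    C <- C + tcrossprod(E)
  }
  Cbar <- C / nRuns
  if (raw) return(Cbar)
  normalizeFC(Cbar)
}

#' Functional connectivity under the stochastic SER protocol
#'
#' Estimates FC from one long run in the stochastic regime (`f > 0` or
#' `p < 1`). The initial condition excites `round(0.1 N)` nodes; the
#' remaining nodes are equipartitioned between susceptible and refractory
#' (any odd remainder goes to S) and assigned at random. Co-activations are
#' accumulated over all `tSteps + 1` recorded time points and normalized.
#'
#' @param net an igraph object.
#' @param params a [SERParams-class] object; the deterministic setting
#'   `f = 0, p = 1` is rejected (use [simulateDeterministicFC()]).
#' @param tSteps length of the run (default 50000).
#' @param seed optional RNG seed.
#' @param raw return the co-activation count matrix instead.
#' @return a [ScoreMatrix-class] of kind `"FC"` (or a matrix if `raw`).
#' @export
simulateStochasticFC <- function(net, params, tSteps = 50000, seed = NULL,
                                 raw = FALSE) {
  .assertNetwork(net)
  if (!is(params, "SERParams")) stop("params must be a SERParams object")
  if (isDeterministic(params))
    stop("f = 0, p = 1 is the deterministic regime; use simulateDeterministicFC()")
  if (tSteps < 1) stop("tSteps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  A <- .adjacency(net)
  n <- nrow(A)
  nE <- round(0.1 * n)
  rest <- n - nE
  nR <- rest %/% 2L
  nS <- rest - nR
  st <- matrix(.randomState(c(nE, nS, nR)), ncol = 1)
  H <- matrix(FALSE, tSteps + 1L, n)
  H[1L, ] <- st[, 1L] == 1L
  for (t in seq_len(tSteps)) {
    st <- .serStepMatrix(A, st, params@f, params@p)
    H[t + 1L, ] <- st[, 1L] == 1L
  }
  C <- crossprod(H + 0)
  if (raw) return(C)
  normalizeFC(C)
}
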