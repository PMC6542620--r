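# Independent oracles, deliberately written with different machinery than
# the implementation (neighbour sets and per-node loops, not adjacency
# matrix algebra).

# topological overlap by explicit common-neighbour counting over node pairs
toOracle <- function(g) {
  n <- igraph::vcount(g)
  nb <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(g, i)))
  to <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    aij <- as.integer(j %in% nb[[i]])
    common <- length(intersect(nb[[i]], nb[[j]]))
    to[i, j] <- (common + aij) /
      (min(length(nb[[i]]), length(nb[[j]])) + 1 - aij)
  }
  to
}

# one deterministic SER update (f = 0, p = 1) via per-node neighbour lists
serStepOracle <- function(nb, s) {
  vapply(seq_along(s), function(i) {
    if (s[i] == 1L) 2L
    else if (s[i] == 2L) 0L
    else if (any(s[nb[[i]]] == 1L)) 1L
    else 0L
  }, integer(1))
}

# exact expected co-activation counts in the deterministic regime, under
# the initial-condition law "composition uniform over all (nE, nS, nR),
# assignment uniform given the composition": enumerate all 3^n states and
# weight each by 1 / (#compositions * #assignments sharing its composition)
serEnumerationOracle <- function(g, tSteps) {
  n <- igraph::vcount(g)
  nb <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(g, i)))
  states <- as.matrix(expand.grid(rep(list(c(0L, 1L, 2L)), n)))
  nComp <- (n + 1) * (n + 2) / 2
  C <- matrix(0, n, n)
  for (k in seq_len(nrow(states))) {
    s <- states[k, ]
    cnt <- c(sum(s == 1L), sum(s == 0L), sum(s == 2L))
    nAssign <- exp(lgamma(n + 1) - sum(lgamma(cnt + 1)))
    w <- 1 / (nComp * nAssign)
    e <- as.numeric(s == 1L)
    Ck <- tcrossprod(e)
    for (t in seq_len(tSteps)) {
      s <- serStepOracle(nb, s)
      e <- as.numeric(s == 1L)
      Ck <- Ck + tcrossprod(e)
    }
    C <- C + w * Ck
  }
  C
}

# chance co-classification level for a partition with module sizes s_m:
# sum_m s_m (s_m - 1) / (N (N - 1))
nullAgreementClosedForm <- function(part) {
  n <- length(part)
  s <- table(part)
  sum(s * (s - 1)) / (n * (n - 1))
}
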