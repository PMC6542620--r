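test_that("serStep applies the synchronous transition rules", {
  tri <- igraph::make_ring(3)
  # (E, S, S) -> (R, E, E): both susceptibles see the excited node
  expect_identical(serStep(tri, c(1L, 0L, 0L), SERParams(0, 1)),
                   c(2L, 1L, 1L))
  # all-S is absorbing without spontaneous activation
  expect_identical(serStep(tri, c(0L, 0L, 0L), SERParams(0, 1)),
                   c(0L, 0L, 0L))
  # refractory nodes stay put when p = 0-ish is not allowed; with p = 1 they recover
  expect_identical(serStep(tri, c(2L, 2L, 2L), SERParams(0, 1)),
                   c(0L, 0L, 0L))
})

test_that("E -> R always, and state counts are conserved", {
  set.seed(1)
  for (i in 1:20) {
    g <- randomGraph(sample(4:15, 1), 0.4)
    n <- igraph::vcount(g)
    st <- sample(0:2, n, replace = TRUE)
    pars <- SERParams(stats::runif(1), stats::runif(1, 0.2, 1))
    hist <- simulateSER(g, st, tSteps = 8, pars)
    for (t in 1:(nrow(hist) - 1)) {
      expect_true(all(hist[t + 1, hist[t, ] == 1L] == 2L))
      expect_length(hist[t, ], n)
      expect_true(all(hist[t, ] %in% 0:2))
    }
  }
})

test_that("coactivation counts joint excitations including t = 0", {
  # node 1 excited at t in {0, 2}; node 2 at t = 2 only
  hist <- rbind(c(1L, 0L, 0L),
                c(2L, 2L, 0L),
                c(1L, 1L, 0L))
  C <- coactivation(hist)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 1], 2)
  expect_equal(C[2, 2], 1)
  expect_true(all(C[, 3] == 0))   # never-excited node
  expect_equal(C, t(C))
})

test_that("coactivation is bounded by the marginal excitation counts", {
  set.seed(2)
  for (i in 1:20) {
    g <- randomGraph(8, 0.5)
    hist <- simulateSER(g, sample(0:2, 8, replace = TRUE), 10,
                        SERParams(0.2, 0.7))
    C <- coactivation(hist)
    d <- diag(C)
    expect_true(all(C <= outer(d, d, pmin) + 1e-12))
    expect_equal(C, t(C))
  }
})

test_that("normalizeFC scales by the smaller excitation count", {
  C <- rbind(c(10, 5, 0),
             c(5, 5, 0),
             c(0, 0, 0))
  fc <- scoreValues(normalizeFC(C))
  expect_equal(fc[1, 2], 1)
  expect_true(all(fc[, 3] == 0))  # zero-denominator convention
  expect_true(all(diag(fc) == 0))
  expect_true(all(fc >= 0 & fc <= 1))
})

test_that("deterministic-regime FC matches the exhaustive-enumeration oracle", {
  # mean co-activation counts over replicate Monte-Carlo estimates must sit
  # within 3 standard errors of the exact expectation; assessed jointly over
  # all tested entries since a few ~3-sigma excursions are expected among
  # hundreds of comparisons
  set.seed(3)
  zAll <- numeric(0)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    g <- randomGraph(n, stats::runif(1, 0.3, 0.8))
    exact <- serEnumerationOracle(g, 8)
    reps <- lapply(1:6, function(r)
      simulateDeterministicFC(g, nRuns = 200, tSteps = 8, raw = TRUE))
    mc <- Reduce(`+`, reps) / 6
    se <- sqrt(Reduce(`+`, lapply(reps, function(m) (m - mc)^2)) / (6 * 5))
    z <- abs(mc - exact) / (se + 0.02 / 3)
    zAll <- c(zAll, z[upper.tri(z, diag = TRUE)])
  }
  expect_gt(mean(zAll <= 3), 0.98)
  expect_lt(max(zAll), 5)
})

test_that("FC respects graph automorphisms on a 6-cycle", {
  g <- igraph::make_ring(6)
  fc <- scoreValues(simulateDeterministicFC(g, nRuns = 4000, tSteps = 12,
                                            seed = 4))
  # all pairs at graph distance 1 are equivalent, likewise distances 2 and 3
  d <- igraph::distances(g)
  for (dist in 1:3) {
    vals <- fc[upper.tri(fc)][d[upper.tri(d)] == dist]
    expect_lt(max(vals) - min(vals), 0.1)
  }
})

test_that("stochastic protocol rejects the deterministic setting and t = 0", {
  g <- randomGraph(10, 0.4)
  expect_error(simulateStochasticFC(g, SERParams(0, 1), tSteps = 100),
               "deterministic")
  expect_error(simulateStochasticFC(g, SERParams(0.1, 0.9), tSteps = 0),
               "tSteps")
})

test_that("high-drive stochastic FC is near-uniform on a vertex-transitive graph", {
  # with f = 1 every susceptible node fires regardless of its neighbours, so
  # the dynamics decouple from the topology and FC flattens across pairs
  g <- igraph::make_ring(8)
  fc <- scoreValues(simulateStochasticFC(g, SERParams(1, 0.9), tSteps = 3000,
                                         seed = 5))
  off <- fc[upper.tri(fc)]
  expect_gt(min(off), 0)
  expect_lt(stats::sd(off) / mean(off), 0.3)
})

test_that("TO and FC are positively correlated in the deterministic regime", {
  g <- generateER(100, 10, seed = 6)
  fc <- simulateDeterministicFC(g, nRuns = 500, tSteps = 30, seed = 7)
  expect_gt(toFcCorrelation(g, fc), 0)
})

test_that("per-run FC normalization is available and bounded", {
  g <- randomGraph(10, 0.5)
  fc <- simulateDeterministicFC(g, nRuns = 50, tSteps = 10, seed = 8,
                                perRunNormalize = TRUE)
  v <- scoreValues(fc)
  expect_true(all(v >= 0 & v <= 1))
})
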