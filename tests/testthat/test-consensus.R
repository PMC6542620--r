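test_that("agreement matrix counts co-classification frequencies", {
  P <- agreementValues(agreementMatrix(list(c(0, 0, 1), c(0, 1, 1))))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[1, 3], 0)
  expect_equal(P[2, 3], 0.5)
  expect_true(all(diag(P) == 1))

  # identical partitions give a 0/1 agreement
  P2 <- agreementValues(agreementMatrix(list(c(1, 1, 2, 2), c(1, 1, 2, 2))))
  expect_true(all(P2 %in% c(0, 1)))

  expect_error(agreementMatrix(list(c(0, 1), c(0, 1, 2))), "length")
  expect_error(agreementMatrix(list()), "at least one")
})

test_that("consensus partitions recover an unambiguous block structure", {
  block <- c(rep(1, 4), rep(2, 4))
  P <- agreementMatrix(replicate(10, block, simplify = FALSE))
  parts <- consensusPartitions(P, n = 5, seed = 1)
  expect_length(parts, 5)
  for (p in parts) expect_equal(partitionOverlap(p, block), 1)

  one <- consensusPartitions(P, n = 1, seed = 2)
  expect_length(one, 1)

  Pflat <- AgreementMatrix(diag(4), nPartitions = 1L)
  expect_error(consensusPartitions(Pflat), "support")
})

test_that("initial agreement is block-exact on disjoint cliques and reproducible", {
  g <- twoCliques(5)
  ia <- initialAgreement(g, nDetect = 20, nConsensus = 5, seed = 3)
  P <- agreementValues(ia$P)
  truth <- rep(1:2, each = 5)
  within <- outer(truth, truth, "==")
  expect_true(all(P[within] == 1))
  expect_true(all(P[!within] == 0))

  ia2 <- initialAgreement(g, nDetect = 20, nConsensus = 5, seed = 3)
  expect_identical(agreementValues(ia2$P), P)
})

test_that("random graphs show degenerate (intermediate) agreement values", {
  g <- generateER(100, 10, seed = 4)
  ia <- initialAgreement(g, nDetect = 50, nConsensus = 5, seed = 5)
  off <- agreementValues(ia$P)[upper.tri(diag(100))]
  expect_gt(sum(off > 0 & off < 1), 100)
})

test_that("partition overlap follows NMI with fixed degenerate conventions", {
  expect_equal(partitionOverlap(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(partitionOverlap(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)

  both <- partitionOverlap(c(1, 1, 1), c(2, 2, 2))
  expect_equal(as.numeric(both), 1)
  expect_true(isTRUE(attr(both, "degenerate")))

  one <- partitionOverlap(c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(as.numeric(one), 0)
  expect_true(isTRUE(attr(one, "degenerate")))

  expect_error(partitionOverlap(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("matrix similarity is an off-diagonal Pearson correlation", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(1, 2, 3)
  m <- m + t(m)
  expect_equal(matrixSimilarity(m, 2 * m), 1)
  m2 <- m
  m2[upper.tri(m2)] <- -c(1, 2, 3)
  m2 <- m2 * upper.tri(m2)
  m2 <- m2 + t(m2)
  expect_equal(matrixSimilarity(m, m2), -1)

  flat <- matrix(1, 3, 3)
  expect_true(is.na(matrixSimilarity(flat, m)))
  expect_true(isTRUE(attr(matrixSimilarity(flat, m), "degenerate")))
  expect_error(matrixSimilarity(m, matrix(0, 2, 2)), "dimensions")
})

test_that("null agreement preserves module sizes and matches the closed form", {
  part <- rep(1:3, c(4, 3, 3))
  # size preservation is exact for every shuffle
  set.seed(6)
  for (i in 1:20) {
    sh <- sample(part)
    expect_equal(sort(unname(table(sh))), sort(unname(table(part))))
  }
  # empirical mean agreement across shuffles matches
  # sum_m s_m (s_m - 1) / (N (N - 1)) within 3 standard errors
  q <- nullAgreementClosedForm(part)
  nShuffles <- 1000
  perShuffle <- vapply(seq_len(nShuffles), function(i) {
    P <- agreementValues(nullAgreement(list(part)))
    mean(P[upper.tri(P)])
  }, numeric(1))
  se <- stats::sd(perShuffle) / sqrt(nShuffles)
  expect_lt(abs(mean(perShuffle) - q), 3 * se + 1e-12)

  # single-module partitions shuffle to themselves
  Pone <- agreementValues(nullAgreement(list(rep(1, 6), rep(1, 6))))
  expect_true(all(Pone == 1))
})

test_that("intramodule density: closed cases and planted-parameter recovery", {
  g <- igraph::make_full_graph(8)
  expect_equal(intramoduleDensity(g, rep(1:2, each = 4)), 1)

  pp <- generatePlantedPartition(100, 4, within = 0.3, between = 0.05,
                                 seed = 7)
  d <- intramoduleDensity(pp$graph, pp$partition)
  # binomial sampling noise around the generator parameter
  expect_lt(abs(d - 0.3), 3 * sqrt(0.3 * 0.7 / choose(25, 2) / 4) + 0.02)

  expect_error(intramoduleDensity(g, 1:8), "singleton")
})

test_that("shuffled-partition intramodule density centres on the graph density", {
  g <- generateER(100, 10, seed = 8)
  set.seed(9)
  parts <- replicate(20, modularityLouvain(g)$partition, simplify = FALSE)
  d <- vapply(1:200, function(i)
    intramoduleDensity(g, sample(parts[[(i - 1) %% 20 + 1]])), numeric(1))
  expect_lt(abs(mean(d) - igraph::edge_density(g)), 0.01)
})

test_that("proto-module analysis recovers planted modules", {
  pp <- generatePlantedPartition(60, 3, within = 0.5, between = 0.05, seed = 10)
  rep <- protoModuleAnalysis(pp$graph, nRuns = 10, nDetectInit = 30,
                             nConsensus = 10, nNull = 20, nDensity = 30,
                             K = 1, seed = 11)
  s <- reportStats(rep)
  # strong planted modules pin down both consensus sets
  expect_gt(s$nmi_consensus, 0.8)
  expect_gt(s$similarity_Pinit_P, 0.8)
  expect_lt(s$p_similarity_Pinit_P, 0.1)
})

test_that("single-run proto-module analysis is flagged as degenerate", {
  g <- generateER(60, 6, seed = 12)
  rep <- protoModuleAnalysis(g, nRuns = 1, nDetectInit = 20, nConsensus = 5,
                             nNull = 10, nDensity = 10, K = 1, seed = 13)
  expect_true(any(grepl("degenerate", reportFlags(rep))))
  expect_true(all(agreementValues(rep@P) %in% c(0, 1)))
})
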