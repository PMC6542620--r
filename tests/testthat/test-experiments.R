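test_that("planted-partition generator honours its parameters", {
  # perfect blocks collapse to disjoint cliques that Louvain recovers exactly
  pp <- generatePlantedPartition(20, 4, within = 1, between = 0, seed = 1)
  expect_equal(igraph::count_components(pp$graph), 4)
  expect_equal(partitionOverlap(modularityLouvain(pp$graph, seed = 2)$partition,
                                pp$partition), 1)

  # realized within-block density tracks the generator parameter
  pp2 <- generatePlantedPartition(100, 4, within = 0.3, between = 0.05,
                                  seed = 3)
  expect_lt(abs(intramoduleDensity(pp2$graph, pp2$partition) - 0.3), 0.05)

  # within = between collapses to ER at matched density
  pp3 <- generatePlantedPartition(100, 4, within = 0.1, between = 0.1, seed = 4)
  expect_lt(abs(igraph::edge_density(pp3$graph) - 0.1), 0.03)

  expect_error(generatePlantedPartition(20, 4, within = 1.2, between = 0),
               "infeasible")
  expect_error(generatePlantedPartition(5, 4, within = 0.5, between = 0.1),
               "at least 2")
})

test_that("runExperiment rejects unknown ids and bad scales", {
  expect_error(runExperiment("fig7_nope", tempdir()), "unknown experiment id")
  expect_error(runExperiment("fig1_trajectory", tempdir(), scale = 0),
               "scale")
})

test_that("trajectory experiment writes a rising mean-Q table and manifest", {
  out <- withr::local_tempdir()
  runExperiment("fig1_trajectory", out, scale = 0.006, seed = 1, nDetect = 2)
  tab <- utils::read.csv(file.path(out, "trajectory.csv"))
  expect_equal(tab$step, 0:30)
  expect_true(all(tab$density == tab$density[1]))
  expect_gt(tab$q_mean[31], tab$q_mean[1])
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_true(man$completed)
  expect_equal(man$experiment, "fig1_trajectory")
  expect_true(file.exists(file.path(out, "initial_graph.edgelist")))
})

test_that("experiments are byte-identical under a fixed seed", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  runExperiment("s5_disconnection", out1, scale = 0.04, seed = 9,
                n = 60, lam = 6, kGrid = c(1, 3))
  runExperiment("s5_disconnection", out2, scale = 0.04, seed = 9,
                n = 60, lam = 6, kGrid = c(1, 3))
  expect_identical(readLines(file.path(out1, "disconnection.csv")),
                   readLines(file.path(out2, "disconnection.csv")))
})

test_that("scaling experiment covers the requested grid", {
  out <- withr::local_tempdir()
  runExperiment("fig1_scaling", out, scale = 0.02, seed = 2,
                nGrid = c(60, 100), lamGrid = c(6, 10), nDetect = 2)
  tab <- utils::read.csv(file.path(out, "scaling.csv"))
  expect_equal(nrow(tab), 4)
  expect_true(all(c("q_final", "n_modules") %in% names(tab)))
})

test_that("disconnection experiment: K = 3 stays connected, high K fragments more", {
  out <- withr::local_tempdir()
  runExperiment("s5_disconnection", out, scale = 0.1, seed = 3,
                kGrid = c(3, 10))
  tab <- utils::read.csv(file.path(out, "disconnection.csv"))
  expect_equal(tab$K, c(3, 10))
  expect_equal(tab$frac_disconnected[tab$K == 3], 0)
  expect_true(tab$n_components_mean[tab$K == 10] >=
                tab$n_components_mean[tab$K == 3])
})

test_that("TR amplifies planted proto-modules (module recovery)", {
  # planted blocks must be weak but detectable: (within - between) N / k
  # above sqrt(mean degree), else no algorithm can align with the truth.
  # within = 0.25, between = 0.05 keeps lambda near 10 with a weak signal.
  pp <- generatePlantedPartition(100, 4, within = 0.25, between = 0.05,
                                 seed = 5)
  set.seed(6)
  truth <- pp$partition
  nmiInit <- mean(vapply(1:20, function(i)
    as.numeric(partitionOverlap(modularityLouvain(pp$graph)$partition, truth)),
    numeric(1)))
  finalParts <- lapply(1:25, function(i)
    modularityLouvain(finalGraph(runTopologicalReinforcement(pp$graph, K = 3,
                                                             nDetect = 0)))$partition)
  cons <- consensusPartitions(agreementMatrix(finalParts), n = 20)
  nmiFinal <- mean(vapply(cons, function(p)
    as.numeric(partitionOverlap(p, truth)), numeric(1)))
  expect_gt(nmiFinal, nmiInit)
})
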