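# scaled replicate count: scale multiplies run counts, never model rules
.scaled <- function(base, scale, floorAt = 2L) {
  max(as.integer(floorAt), as.integer(round(base * scale)))
}

.writeManifest <- function(outDir, id, scale, seed, params, completed,
                           errors = character(0)) {
  manifest <- list(experiment = id, scale = scale, seed = seed,
                   params = params,
                   package = "TopoRewire",
                   package_version = as.character(utils::packageVersion("TopoRewire")),
                   r_version = R.version.string,
                   completed = completed, errors = errors)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a named experiment pipeline at configurable scale
#'
#' End-to-end runners for the package's standard experiments, each writing
#' tidy CSV tables plus a JSON manifest (seeds, parameters, versions,
#' completion status) to `outDir`, sufficient to regenerate the underlying
#' numbers. `scale` in (0, 1] multiplies replicate counts only — never
#' model rules, network sizes or windows — with small floors so the
#' qualitative behaviour is preserved. Runs are fully reproducible: the
#' same id, scale and seed yield byte-identical CSV output.
#'
#' Available ids:
#' \describe{
#'   \item{`fig1_trajectory`}{TR trajectories (Q, module count vs step)
#'     from one ER(100, 10) graph, averaged across runs; also writes final
#'     edge lists for the first runs.}
#'   \item{`fig1_scaling`}{final Q and module count over a grid of network
#'     sizes and mean degrees.}
#'   \item{`fig3_proto`}{the proto-module analysis pipeline; writes its
#'     statistics and distribution tables.}
#'   \item{`fig5_sweep`}{TO-FC correlation vs modularity gain of the
#'     Hebbian rule over SER settings.}
#'   \item{`fig6_correspondence`}{similarity of TR and Hebbian agreement
#'     matrices for a modular (deterministic) and a nonmodular
#'     (high-drive stochastic) setting.}
#'   \item{`s5_disconnection`}{component counts of TR-evolved networks for
#'     K = 1..10.}
#' }
#'
#' @param id experiment id (see above).
#' @param outDir output directory (created if needed).
#' @param scale replicate-count scale factor in (0, 1].
#' @param seed RNG seed for the whole experiment.
#' @param ... experiment-specific overrides: `n`, `lam`, `K`, `nDetect`,
#'   `nGrid`, `lamGrid`, `kGrid`, `grid` (sweep settings data.frame),
#'   `windowRuns`, `windowSteps`, `stochSteps`.
#' @return invisibly, the vector of files written.
#' @export
runExperiment <- function(id, outDir, scale = 1, seed = 1, ...) {
  ids <- c("fig1_trajectory", "fig1_scaling", "fig3_proto", "fig5_sweep",
           "fig6_correspondence", "s5_disconnection")
  if (!is.character(id) || length(id) != 1L || !id %in% ids)
    stop("unknown experiment id; must be one of: ", paste(ids, collapse = ", "))
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  dots <- list(...)
  opt <- function(name, default) if (is.null(dots[[name]])) default else dots[[name]]
  n <- opt("n", 100); lam <- opt("lam", 10); K <- opt("K", 3)
  nDetect <- opt("nDetect", 5)
  files <- character(0)
  errors <- character(0)
  params <- list(n = n, lam = lam, K = K, nDetect = nDetect)

  if (id == "fig1_trajectory") {
    nRuns <- .scaled(500, scale)
    params$nRuns <- nRuns
    g0 <- generateER(n, lam)
    seeds <- .childSeeds(nRuns)
    recs <- lapply(seq_len(nRuns), function(i)
      trajectoryRecords(runTopologicalReinforcement(g0, K = K,
                                                    nDetect = nDetect,
                                                    seed = seeds[i])))
    steps <- recs[[1L]]$step
    qm <- sapply(recs, function(r) r$q_mean)
    nm <- sapply(recs, function(r) r$n_modules_mean)
    nc <- sapply(recs, function(r) r$n_components)
    tab <- data.frame(step = steps,
                      q_mean = rowMeans(qm), q_std = apply(qm, 1, stats::sd),
                      n_modules_mean = rowMeans(nm),
                      density = recs[[1L]]$density,
                      n_components = rowMeans(nc))
    f <- file.path(outDir, "trajectory.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    for (i in seq_len(min(5L, nRuns))) {
      tr <- runTopologicalReinforcement(g0, K = K, nDetect = 0, seed = seeds[i])
      fe <- file.path(outDir, sprintf("final_graph_run%02d.edgelist", i))
      writeEdgeList(finalGraph(tr), fe)
      files <- c(files, fe)
    }
    fe <- file.path(outDir, "initial_graph.edgelist")
    writeEdgeList(g0, fe)
    files <- c(files, fe)
  }

  if (id == "fig1_scaling") {
    nGrid <- opt("nGrid", seq(60, 500, by = 40))
    lamGrid <- opt("lamGrid", seq(6, 20, by = 2))
    reps <- .scaled(50, scale, floorAt = 1L)
    params <- c(params, list(nGrid = nGrid, lamGrid = lamGrid, reps = reps))
    rows <- list()
    for (nn in nGrid) for (ll in lamGrid) {
      if (ll > nn - 1) next
      cell <- tryCatch({
        res <- vapply(seq_len(reps), function(i) {
          tr <- runTopologicalReinforcement(generateER(nn, ll), K = K,
                                            nDetect = 0)
          det <- vapply(seq_len(nDetect), function(k) {
            r <- modularityLouvain(finalGraph(tr))
            c(r$q, r$nModules)
          }, numeric(2))
          c(mean(det[1, ]), mean(det[2, ]))
        }, numeric(2))
        data.frame(n = nn, lam = ll, q_final = mean(res[1, ]),
                   q_final_sd = stats::sd(res[1, ]),
                   n_modules = mean(res[2, ]))
      }, error = function(e) {
        errors <<- c(errors, sprintf("n=%d lam=%d: %s", nn, ll,
                                     conditionMessage(e)))
        NULL
      })
      rows[[length(rows) + 1L]] <- cell
    }
    f <- file.path(outDir, "scaling.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }

  if (id == "fig3_proto") {
    nRuns <- .scaled(500, scale, floorAt = 10L)
    nDetectInit <- .scaled(500, scale, floorAt = 50L)
    nConsensus <- .scaled(100, scale, floorAt = 10L)
    nNull <- .scaled(100, scale, floorAt = 20L)
    nDensity <- .scaled(500, scale, floorAt = 50L)
    params <- c(params, list(nRuns = nRuns, nDetectInit = nDetectInit,
                             nConsensus = nConsensus, nNull = nNull,
                             nDensity = nDensity))
    g0 <- generateER(n, lam)
    rep <- protoModuleAnalysis(g0, nRuns = nRuns, nDetectInit = nDetectInit,
                               nConsensus = nConsensus, nNull = nNull,
                               nDensity = nDensity, K = K)
    f <- file.path(outDir, "proto_stats.json")
    jsonlite::write_json(reportStats(rep), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    for (nm in names(reportTables(rep))) {
      ft <- file.path(outDir, paste0("proto_", nm, ".csv"))
      utils::write.csv(reportTables(rep)[[nm]], ft, row.names = FALSE)
      files <- c(files, ft)
    }
  }

  if (id == "fig5_sweep") {
    nRuns <- .scaled(150, scale, floorAt = 2L)
    windowRuns <- opt("windowRuns", 500)
    windowSteps <- opt("windowSteps", 30)
    stochSteps <- opt("stochSteps", 5000)
    grid <- opt("grid", {
      stoch <- expand.grid(f = 10^seq(-4, 0, length.out = 10),
                           p = seq(0.1, 1, length.out = 10))
      stoch$regime <- "stochastic"
      stoch$e <- NA_real_; stoch$s <- NA_real_; stoch$r <- NA_real_
      det <- expand.grid(e = seq(0.05, 0.95, by = 0.1),
                         s = seq(0.05, 0.95, by = 0.1))
      det <- det[det$e + det$s < 1, ]
      det$r <- 1 - det$e - det$s
      det$regime <- "deterministic"
      det$f <- NA_real_; det$p <- NA_real_
      rbind(stoch[c("regime", "f", "p", "e", "s", "r")],
            det[c("regime", "f", "p", "e", "s", "r")])
    })
    params <- c(params, list(nRuns = nRuns, windowRuns = windowRuns,
                             windowSteps = windowSteps,
                             stochSteps = stochSteps, nCells = nrow(grid)))
    g0 <- generateER(n, lam)
    tab <- parameterSweep(g0, grid, nRuns = nRuns, K = K, nDetect = nDetect,
                          windowRuns = windowRuns, windowSteps = windowSteps,
                          stochSteps = stochSteps)
    f <- file.path(outDir, "sweep.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  if (id == "fig6_correspondence") {
    nRuns <- .scaled(500, scale, floorAt = 5L)
    windowRuns <- opt("windowRuns", 500)
    windowSteps <- opt("windowSteps", 30)
    stochSteps <- opt("stochSteps", 5000)
    params <- c(params, list(nRuns = nRuns, windowRuns = windowRuns,
                             windowSteps = windowSteps,
                             stochSteps = stochSteps))
    g0 <- generateER(n, lam)
    trParts <- lapply(seq_len(nRuns), function(i)
      modularityLouvain(finalGraph(runTopologicalReinforcement(g0, K = K,
                                                               nDetect = 0)))$partition)
    Ptr <- agreementMatrix(trParts)
    settings <- list(
      deterministic = function()
        runHebbian(g0, SERParams(0, 1), K = K, nDetect = 0,
                   windowRuns = windowRuns, windowSteps = windowSteps),
      stochastic_highf = function()
        runHebbian(g0, SERParams(0.9, 0.9), K = K, nDetect = 0,
                   stochSteps = stochSteps))
    rows <- lapply(names(settings), function(nmSet) {
      hebParts <- lapply(seq_len(nRuns), function(i)
        modularityLouvain(finalGraph(settings[[nmSet]]()))$partition)
      Pheb <- agreementMatrix(hebParts)
      Pnull <- nullAgreement(hebParts)
      data.frame(setting = nmSet,
                 similarity_TR_Hebbian =
                   as.numeric(matrixSimilarity(agreementValues(Ptr),
                                               agreementValues(Pheb))),
                 similarity_TR_null =
                   as.numeric(matrixSimilarity(agreementValues(Ptr),
                                               agreementValues(Pnull))))
    })
    f <- file.path(outDir, "correspondence.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }

  if (id == "s5_disconnection") {
    kGrid <- opt("kGrid", 1:10)
    reps <- .scaled(50, scale, floorAt = 2L)
    params <- c(params, list(kGrid = kGrid, reps = reps))
    rows <- list()
    for (kk in kGrid) {
      nc <- vapply(seq_len(reps), function(i) {
        tr <- runTopologicalReinforcement(generateER(n, lam), K = kk,
                                          nDetect = 0)
        utils::tail(trajectoryRecords(tr)$n_components, 1)
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(K = kk, n_components_mean = mean(nc),
                   frac_disconnected = mean(nc > 1))
    }
    f <- file.path(outDir, "disconnection.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }

  .writeManifest(outDir, id, scale, seed, params,
                 completed = length(errors) == 0L, errors = errors)
  files <- c(files, file.path(outDir, "manifest.json"))
  invisible(files)
}
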