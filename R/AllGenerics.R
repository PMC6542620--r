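#' Accessors for TopoRewire containers
#'
#' Small accessor generics: `scoreValues`/`scoreKind` for [ScoreMatrix-class]
#' objects, `agreementValues`/`nPartitions` for [AgreementMatrix-class],
#' `trajectoryRecords`/`finalGraph`/`trajectorySnapshots` for
#' [Trajectory-class], `isDeterministic` for [SERParams-class] and
#' `reportStats`/`reportTables`/`reportFlags` for [ProtoModuleReport-class].
#'
#' @param x the object.
#' @return the slot content (a matrix, data.frame, list, igraph or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("scoreKind", function(x) standardGeneric("scoreKind"))
#' @rdname accessors
#' @export
setGeneric("agreementValues", function(x) standardGeneric("agreementValues"))
#' @rdname accessors
#' @export
setGeneric("nPartitions", function(x) standardGeneric("nPartitions"))
#' @rdname accessors
#' @export
setGeneric("trajectoryRecords", function(x) standardGeneric("trajectoryRecords"))
#' @rdname accessors
#' @export
setGeneric("finalGraph", function(x) standardGeneric("finalGraph"))
#' @rdname accessors
#' @export
setGeneric("trajectorySnapshots", function(x) standardGeneric("trajectorySnapshots"))
#' @rdname accessors
#' @export
setGeneric("isDeterministic", function(x) standardGeneric("isDeterministic"))
#' @rdname accessors
#' @export
setGeneric("reportStats", function(x) standardGeneric("reportStats"))
#' @rdname accessors
#' @export
setGeneric("reportTables", function(x) standardGeneric("reportTables"))
#' @rdname accessors
#' @export
setGeneric("reportFlags", function(x) standardGeneric("reportFlags"))

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("scoreKind", "ScoreMatrix", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("agreementValues", "AgreementMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nPartitions", "AgreementMatrix", function(x) x@nPartitions)
#' @rdname accessors
#' @export
setMethod("trajectoryRecords", "Trajectory", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("finalGraph", "Trajectory", function(x) x@graph)
#' @rdname accessors
#' @export
setMethod("trajectorySnapshots", "Trajectory", function(x) x@snapshots)
#' @rdname accessors
#' @export
setMethod("isDeterministic", "SERParams", function(x) x@f == 0 && x@p == 1)
#' @rdname accessors
#' @export
setMethod("reportStats", "ProtoModuleReport", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("reportTables", "ProtoModuleReport", function(x) x@tables)
#' @rdname accessors
#' @export
setMethod("reportFlags", "ProtoModuleReport", function(x) x@flags)

setMethod("show", "ScoreMatrix", function(object) {
  v <- object@values
  cat(sprintf("ScoreMatrix (%s) %d x %d, range [%.3f, %.3f]\n",
              object@kind, nrow(v), ncol(v),
              min(v[upper.tri(v)]), max(v[upper.tri(v)])))
})

setMethod("show", "AgreementMatrix", function(object) {
  v <- object@values
  cat(sprintf("AgreementMatrix %d x %d from %d partitions, mean off-diagonal %.3f\n",
              nrow(v), ncol(v), object@nPartitions, mean(v[upper.tri(v)])))
})

setMethod("show", "SERParams", function(object) {
  cat(sprintf("SERParams: f = %g, p = %g (%s regime)\n", object@f, object@p,
              if (isDeterministic(object)) "deterministic" else "stochastic"))
})

setMethod("show", "Trajectory", function(object) {
  r <- object@records
  cat(sprintf("Trajectory (%s rule): %d steps, density %.4f\n",
              if (is.null(object@config$rule)) "?" else object@config$rule,
              max(r$step), r$density[1]))
  if (!all(is.na(r$q_mean)))
    cat(sprintf("  Q: %.3f -> %.3f;  modules: %.1f -> %.1f\n",
                r$q_mean[1], r$q_mean[nrow(r)],
                r$n_modules_mean[1], r$n_modules_mean[nrow(r)]))
  cat(sprintf("  final components: %d;  snapshots kept: %d\n",
              r$n_components[nrow(r)], length(object@snapshots)))
})

setMethod("show", "ProtoModuleReport", function(object) {
  s <- object@stats
  cat("ProtoModuleReport\n")
  for (nm in names(s)) {
    if (is.numeric(s[[nm]]) && length(s[[nm]]) == 1L)
      cat(sprintf("  %s: %.4f\n", nm, s[[nm]]))
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
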