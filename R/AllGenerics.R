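## Accessor generics shared by the result classes.

#' Per-gene stability values of a result object
#'
#' Lower values always mean more stable expression, whatever the method.
#' For `BestkeeperResult` the value returned is the CV (percent) used as
#' the primary ranking key.
#'
#' @param x a `GenormResult`, `NormfinderResult` or `BestkeeperResult`.
#' @return named numeric vector.
#' @export
setGeneric("stability", function(x) standardGeneric("stability"))

#' Gene ranking of a result object, most stable first
#'
#' @param x a result object (`GenormResult`, `NormfinderResult`,
#'   `BestkeeperResult`, `ComparativeRanking` or `ScreeningReport`).
#' @return character vector of gene symbols.
#' @export
setGeneric("geneRanking", function(x) standardGeneric("geneRanking"))

#' Candidate genes retained by a screening report
#'
#' @param x a `ScreeningReport`.
#' @return character vector.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' Sample design table of an expression or Ct container
#'
#' @param x an `ExpressionTable` or `CtTable`.
#' @return data.frame with sample_id, organ, stage, replicate.
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' Per-gene amplification efficiencies of a CtTable
#'
#' @param x a `CtTable`.
#' @return named numeric vector in (1, 2.2].
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))

#' @rdname designTable
#' @export
setMethod("designTable", "SummarizedExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  rownames(cd) <- NULL
  cd
})

#' @rdname efficiencies
#' @export
setMethod("efficiencies", "CtTable", function(x)
  setNames(rowData(x)$efficiency, rownames(x)))

#' @rdname stability
#' @export
setMethod("stability", "GenormResult", function(x) x@stability)
#' @rdname stability
#' @export
setMethod("stability", "NormfinderResult", function(x) x@stability)
#' @rdname stability
#' @export
setMethod("stability", "BestkeeperResult", function(x)
  setNames(x@stats$cv_pct, x@stats$gene))

#' @rdname geneRanking
#' @export
setMethod("geneRanking", "GenormResult", function(x) x@ranking)
#' @rdname geneRanking
#' @export
setMethod("geneRanking", "NormfinderResult", function(x) x@ranking)
#' @rdname geneRanking
#' @export
setMethod("geneRanking", "BestkeeperResult", function(x)
  x@stats$gene[order(x@stats$rank)])
#' @rdname geneRanking
#' @export
setMethod("geneRanking", "ComparativeRanking", function(x)
  x@table$gene[order(x@table$final_rank)])

#' @rdname candidates
#' @export
setMethod("candidates", "ScreeningReport", function(x) x@candidates)

## show methods -------------------------------------------------------------

setMethod("show", "ScreeningReport", function(object) {
  cat(sprintf("ScreeningReport: %d (gene, group) cells, %d candidate gene(s)\n",
              nrow(object@stats), length(object@candidates)))
  cat(sprintf("  thresholds: CV <= %.2f%%, MFC <= %.2f (rounded to %d dp), >= %d group(s)\n",
              object@thresholds$cv_max, object@thresholds$mfc_max,
              object@thresholds$rounding_dp, object@thresholds$min_groups))
  if (length(object@excluded) > 0)
    cat("  exempt from screen:", paste(object@excluded, collapse = ", "), "\n")
  cat("  candidates:", paste(object@candidates, collapse = ", "), "\n")
})

setMethod("show", "GenormResult", function(object) {
  cat(sprintf("GenormResult: %d genes\n", length(object@stability)))
  cat(sprintf("  most stable pair: %s (M = %.4f)\n",
              paste(object@stablePair, collapse = " / "),
              object@stability[object@stablePair[1]]))
  rn <- if (is.na(object@recommendedN)) "not achieved" else object@recommendedN
  cat(sprintf("  recommended number of reference genes (V < %.2f): %s\n",
              object@cutoff, rn))
})

setMethod("show", "NormfinderResult", function(object) {
  cat(sprintf("NormfinderResult (%s): %d genes; most stable: %s (%.4f)\n",
              object@mode, length(object@stability), object@ranking[1],
              object@stability[object@ranking[1]]))
})

setMethod("show", "BestkeeperResult", function(object) {
  top <- object@stats[which.min(object@stats$rank), ]
  cat(sprintf("BestkeeperResult: %d genes, %d samples in index; best: %s (CV %.3f%% +/- SD %.3f)\n",
              nrow(object@stats), length(object@index), top$gene, top$cv_pct,
              top$sd))
})

setMethod("show", "ComparativeRanking", function(object) {
  cat(sprintf("ComparativeRanking (%s aggregation): %d genes; top: %s\n",
              object@method, nrow(object@table),
              object@table$gene[which.min(object@table$final_rank)]))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d genes, %d organs x %d stages x %d replicates (seed %d)\n",
              length(object@genes), length(object@organs),
              length(object@stages), object@replicates, object@seed))
})
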