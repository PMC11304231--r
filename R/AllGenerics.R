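# Generics, accessors and show methods.

#' @include AllClasses.R
NULL

#' Accessors for SpyTools objects
#'
#' Slot accessors for the core S4 classes. Use these instead of `@`.
#'
#' @param x An object of the documented class.
#' @return The slot value; see the class documentation for semantics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tirLeft", function(x) standardGeneric("tirLeft"))
#' @rdname accessors
#' @export
setGeneric("tirRight", function(x) standardGeneric("tirRight"))
#' @rdname accessors
#' @export
setGeneric("tirIdentity", function(x) standardGeneric("tirIdentity"))
#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setGeneric("kdistance", function(x) standardGeneric("kdistance"))
#' @rdname accessors
#' @export
setGeneric("isSaturated", function(x) standardGeneric("isSaturated"))
#' @rdname accessors
#' @export
setGeneric("alignedBp", function(x) standardGeneric("alignedBp"))
#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname accessors
#' @export
setGeneric("attrition", function(x) standardGeneric("attrition"))
#' @rdname accessors
#' @export
setGeneric("baseFreq", function(x) standardGeneric("baseFreq"))
#' @rdname accessors
#' @export
setGeneric("infoContent", function(x) standardGeneric("infoContent"))
#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))
#' @rdname accessors
#' @export
setGeneric("combinedFraction", function(x) standardGeneric("combinedFraction"))
#' @rdname accessors
#' @export
setGeneric("criterionFractions",
           function(x) standardGeneric("criterionFractions"))

#' @rdname accessors
setMethod("tirLeft", "TirPair", function(x) x@left)
#' @rdname accessors
setMethod("tirRight", "TirPair", function(x) x@right)
#' @rdname accessors
setMethod("tirIdentity", "TirPair", function(x) x@identity)
#' @rdname accessors
setMethod("tirLeft", "TransposonElement",
          function(x) if (is.null(x@tirs)) NULL else x@tirs@left)
#' @rdname accessors
setMethod("tirRight", "TransposonElement",
          function(x) if (is.null(x@tirs)) NULL else x@tirs@right)
#' @rdname accessors
setMethod("classification", "TransposonElement", function(x) x@classification)
#' @rdname accessors
setMethod("kdistance", "DivergenceEstimate", function(x) x@K)
#' @rdname accessors
setMethod("isSaturated", "DivergenceEstimate", function(x) x@saturated)
#' @rdname accessors
setMethod("alignedBp", "DivergenceEstimate", function(x) x@alignedBp)
#' @rdname accessors
setMethod("sites", "InsertionSiteSet", function(x) x@sites)
#' @rdname accessors
setMethod("attrition", "InsertionSiteSet", function(x) x@attrition)
#' @rdname accessors
setMethod("baseFreq", "LogoMatrix", function(x) x@freq)
#' @rdname accessors
setMethod("infoContent", "LogoMatrix", function(x) x@infoContent)
#' @rdname accessors
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)
#' @rdname accessors
setMethod("combinedFraction", "GshReport", function(x) x@combined)
#' @rdname accessors
setMethod("criterionFractions", "GshReport", function(x) x@perCriterion)

setMethod("show", "TirPair", function(object) {
  cat(sprintf("TirPair: %d bp, identity %.3f | left %d-%d, right %d-%d\n",
              IRanges::width(object@left), object@identity,
              IRanges::start(object@left), IRanges::end(object@left),
              IRanges::start(object@right), IRanges::end(object@right)))
})

setMethod("show", "TransposonElement", function(object) {
  cat(sprintf("TransposonElement '%s' (%d bp): %s\n", object@id,
              length(object@sequence), object@classification))
  if (!is.null(object@tirs)) {
    cat("  TIRs: "); show(object@tirs)
  } else cat("  TIRs: none detected\n")
  cat(sprintf("  transposase: %d aa, DBD %s, DDE %s\n",
              object@proteinLength,
              if (object@hasDbd) "yes" else "no",
              if (object@hasDde) "yes" else "no"))
  if (!is.na(object@flank5))
    cat(sprintf("  flanks: 5'-%s / %s-3'\n", object@flank5, object@flank3))
})

setMethod("show", "DivergenceEstimate", function(object) {
  if (object@saturated || is.na(object@K)) {
    cat(sprintf("DivergenceEstimate '%s': saturated/undefined (P=%.4f Q=%.4f, %d bp)\n",
                object@copyId, object@P, object@Q, object@alignedBp))
  } else {
    cat(sprintf("DivergenceEstimate '%s': K = %.4f (P=%.4f Q=%.4f, %d bp)\n",
                object@copyId, object@K, object@P, object@Q, object@alignedBp))
  }
})

setMethod("show", "DivergenceLandscape", function(object) {
  cat(sprintf("DivergenceLandscape: %d copies, %d bins, %.0f bp total coverage",
              object@nCopies, length(object@coverage), sum(object@coverage)))
  if (object@saturatedBp > 0)
    cat(sprintf(" (+%.0f bp saturated, excluded)", object@saturatedBp))
  cat("\n")
})

setMethod("show", "InsertionSiteSet", function(object) {
  cat(sprintf("InsertionSiteSet: %d sites (min support %s, dedup by molecule: %s)\n",
              length(object@sites),
              object@params$minSupport %||% "?",
              object@params$dedupeByMolecule %||% "?"))
})

setMethod("show", "LogoMatrix", function(object) {
  cat(sprintf("LogoMatrix: %d positions from %d windows; info content %.2f-%.2f bits\n",
              ncol(object@freq), object@nWindows,
              min(object@infoContent), max(object@infoContent)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d categories vs %d random loci\n",
              nrow(object@table), object@nRandom))
  print(object@table, row.names = FALSE)
})

setMethod("show", "GshReport", function(object) {
  cat(sprintf("GshReport over %d sites: combined %.1f%% in safe harbors\n",
              object@nSites, 100 * object@combined))
  for (nm in names(object@perCriterion))
    cat(sprintf("  %-28s %.1f%%\n", nm, 100 * object@perCriterion[[nm]]))
})

setMethod("show", "SpySimConfig", function(object) {
  cat(sprintf(paste0("SpySimConfig: seed %d, genome %d bp (GC %.2f), ",
                     "%.1f motifs/kb, %d copies, %d sites (%.0f%% at motif)\n"),
              object@seed, object@genomeLength, object@gcContent,
              object@motifDensity, nrow(object@copyDivergences),
              object@nSites, 100 * object@targetMotifFraction))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
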