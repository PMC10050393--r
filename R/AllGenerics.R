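#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: `spotId()` returns
#' the spot identifier, `pixels()` the raw pixel array, `nTiles()` the number
#' of tiles in a bag, `tileCoords()` the 0-based grid coordinates,
#' `stainMatrix()` and `maxConcentrations()` the stain system of a
#' [StainProfile-class], `confusion()` the confusion matrix of a
#' [MetricsReport-class], and `heatmapValues()` the grid of a
#' [Heatmap-class].
#'
#' @param object an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spotId", function(object) standardGeneric("spotId"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("nTiles", function(object) standardGeneric("nTiles"))

#' @rdname accessors
#' @export
setGeneric("tileCoords", function(object) standardGeneric("tileCoords"))

#' @rdname accessors
#' @export
setGeneric("stainMatrix", function(object) standardGeneric("stainMatrix"))

#' @rdname accessors
#' @export
setGeneric("maxConcentrations",
           function(object) standardGeneric("maxConcentrations"))

#' @rdname accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname accessors
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))

#' @rdname accessors
#' @export
setGeneric("cohortImages", function(object) standardGeneric("cohortImages"))

setMethod("spotId", "SpotImage", function(object) object@spotId)
setMethod("spotId", "TileBag", function(object) object@spotId)
setMethod("pixels", "SpotImage", function(object) object@pixels)
setMethod("nTiles", "TileBag", function(object) length(object@tiles))
setMethod("tileCoords", "TileBag", function(object) object@coords)
setMethod("stainMatrix", "StainProfile", function(object) object@stainMatrix)
setMethod("maxConcentrations", "StainProfile",
          function(object) object@maxConcentrations)
setMethod("confusion", "MetricsReport", function(object) object@confusion)
setMethod("heatmapValues", "Heatmap", function(object) object@values)
setMethod("cohortLabels", "SyntheticCohort", function(object) object@labels)
setMethod("cohortImages", "SyntheticCohort", function(object) object@images)

setMethod("show", "SpotImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SpotImage '%s': %d x %d RGB", object@spotId, d[1], d[2]))
  if (!is.null(object@metadata$scaleFactor))
    cat(sprintf(" (downscaled by %.2f)", object@metadata$scaleFactor))
  cat("\n")
})

setMethod("show", "TileBag", function(object) {
  cat(sprintf("TileBag '%s': %d tiles of %d px on a %d x %d grid\n",
              object@spotId, length(object@tiles), object@tileSize,
              object@gridDim[1], object@gridDim[2]))
})

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (rows: hematoxylin, dab, residual)\n")
  M <- round(object@stainMatrix, 4)
  rownames(M) <- c("hematoxylin", "dab", "residual")
  colnames(M) <- c("R", "G", "B")
  print(M)
  cat(sprintf("robust max concentrations: H %.3f, DAB %.3f\n",
              object@maxConcentrations[1], object@maxConcentrations[2]))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (confusion is predicted x true)\n")
  print(object@confusion)
  cat(sprintf("balanced accuracy : %.4f\n", object@balancedAccuracy))
  cat(sprintf("weighted precision: %.4f\n", object@weightedPrecision))
  cat(sprintf("weighted recall   : %.4f\n", object@weightedRecall))
  cat(sprintf("weighted F1       : %.4f\n", object@weightedF1))
  if (length(object@perClassAUC)) {
    cat("per-class AUC     :",
        paste(sprintf("%s=%.3f", names(object@perClassAUC),
                      object@perClassAUC), collapse = " "), "\n")
  }
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap %d x %d, %d missing cells%s\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values)),
              if (object@constant) " (constant map)" else ""))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(factor(object@labels$ihc_score, levels = 0:3))
  cat(sprintf("SyntheticCohort: %d spots (%s regime), scores 0/1/2/3 = %s\n",
              length(object@images),
              object@config$regime %||% "unknown",
              paste(as.integer(tab), collapse = "/")))
})
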