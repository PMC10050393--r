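#' @import methods
NULL

#' SpotImage: one RGB tissue-microarray spot
#'
#' An 8-bit RGB image of a single TMA spot together with its identifier.
#' Pixel values are stored as a numeric `H x W x 3` array on the `[0, 255]`
#' scale (channel order R, G, B).
#'
#' @slot pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @slot spotId single character identifier of the spot.
#' @slot micronsPerPixel optional physical pixel size hint (`NA` if unknown).
#' @slot metadata free-form list (e.g. the scale factor after downscaling).
#'
#' @seealso [SpotImage()], [tileImage()], [downscaleImage()]
#' @exportClass SpotImage
setClass("SpotImage",
  representation(
    pixels = "array",
    spotId = "character",
    micronsPerPixel = "numeric",
    metadata = "list"
  ),
  prototype(
    micronsPerPixel = NA_real_,
    metadata = list()
  )
)

setValidity("SpotImage", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'pixels' must be an H x W x 3 array")
  else if (d[1] < 1L || d[2] < 1L)
    msg <- c(msg, "image must have H >= 1 and W >= 1")
  if (length(d) == 3L && d[3] == 3L) {
    rng <- range(object@pixels)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "channel values must be finite and within [0, 255]")
  }
  if (length(object@spotId) != 1L || is.na(object@spotId))
    msg <- c(msg, "'spotId' must be a single non-NA string")
  if (length(msg)) msg else TRUE
})

#' TileBag: the multiple-instance unit for one spot
#'
#' An ordered collection of square tiles cut from one spot image, each tagged
#' with its 0-based position on the tile grid. Tiles are stored row-major
#' (left-to-right, top-to-bottom), which keeps attention maps reproducible.
#'
#' @slot tiles list of `ts x ts x 3` pixel arrays.
#' @slot coords integer matrix with columns `grid_row`, `grid_col` (0-based).
#' @slot spotId spot identifier shared by all tiles.
#' @slot tileSize tile side length in pixels.
#' @slot gridDim integer vector `c(rows, cols)` of the full tile grid.
#'
#' @seealso [tileImage()], [tileFeatures()], [reassembleTiles()]
#' @exportClass TileBag
setClass("TileBag",
  representation(
    tiles = "list",
    coords = "matrix",
    spotId = "character",
    tileSize = "integer",
    gridDim = "integer"
  )
)

setValidity("TileBag", function(object) {
  msg <- character()
  n <- length(object@tiles)
  ts <- object@tileSize
  if (nrow(object@coords) != n)
    msg <- c(msg, "'coords' must have one row per tile")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "'coords' must have columns grid_row, grid_col")
  if (length(object@gridDim) != 2L || any(object@gridDim < 1L))
    msg <- c(msg, "'gridDim' must be two positive integers")
  if (n > 0L) {
    key <- paste(object@coords[, 1], object@coords[, 2])
    if (anyDuplicated(key))
      msg <- c(msg, "no two tiles may share a grid cell")
    if (any(object@coords < 0L) ||
        any(object@coords[, 1] >= object@gridDim[1]) ||
        any(object@coords[, 2] >= object@gridDim[2]))
      msg <- c(msg, "grid coordinates must lie within gridDim")
    ok <- vapply(object@tiles, function(t) {
      d <- dim(t)
      length(d) == 3L && d[1] == ts && d[2] == ts && d[3] == 3L
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf("all tiles must be %d x %d x 3 arrays", ts, ts))
  }
  if (length(msg)) msg else TRUE
})

#' StainProfile: the 3x3 stain system of an H-DAB slide
#'
#' Rows of `stainMatrix` are unit-norm optical-density vectors for
#' hematoxylin, DAB and a residual channel (in that order).
#' `maxConcentrations` holds robust (99th percentile) per-stain maxima for
#' hematoxylin and DAB, used when rescaling concentrations during stain
#' normalization.
#'
#' @slot stainMatrix 3x3 numeric matrix, rows unit-norm, nonsingular.
#' @slot maxConcentrations positive numeric of length 2 (hematoxylin, DAB).
#'
#' @seealso [rjHDABProfile()], [macenkoEstimate()], [deconvolveStains()]
#' @exportClass StainProfile
setClass("StainProfile",
  representation(
    stainMatrix = "matrix",
    maxConcentrations = "numeric"
  )
)

setValidity("StainProfile", function(object) {
  msg <- character()
  M <- object@stainMatrix
  if (!all(dim(M) == c(3L, 3L))) {
    msg <- c(msg, "'stainMatrix' must be 3 x 3")
  } else {
    norms <- sqrt(rowSums(M^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "stain matrix rows must have unit Euclidean norm")
    if (abs(det(M)) < 1e-8)
      msg <- c(msg, "stain matrix must be nonsingular")
  }
  if (length(object@maxConcentrations) != 2L ||
      any(object@maxConcentrations <= 0))
    msg <- c(msg, "'maxConcentrations' must be 2 positive numbers")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: classifier performance summary
#'
#' Confusion matrix plus the scalar metrics reported for HER2 scoring:
#' balanced accuracy (unweighted macro-average of per-class recall) and
#' support-weighted precision/recall/F1, with optional per-class one-vs-all
#' AUCs. The confusion matrix is oriented predicted x true: entry (i, j)
#' counts spots predicted as class i whose true class is j.
#'
#' @slot confusion numeric C x C matrix, rows = predicted, columns = true.
#' @slot balancedAccuracy unweighted mean of per-class recall.
#' @slot weightedPrecision support-weighted precision.
#' @slot weightedRecall support-weighted recall (equals overall accuracy).
#' @slot weightedF1 support-weighted F1.
#' @slot perClassAUC named numeric of one-vs-all AUCs (`NA` when undefined).
#'
#' @seealso [evaluatePredictions()], [balancedAccuracy()], [weightedMetrics()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    confusion = "matrix",
    balancedAccuracy = "numeric",
    weightedPrecision = "numeric",
    weightedRecall = "numeric",
    weightedF1 = "numeric",
    perClassAUC = "numeric"
  ),
  prototype(perClassAUC = numeric())
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "'confusion' must be square")
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be non-negative")
  sc <- c(object@balancedAccuracy, object@weightedPrecision,
          object@weightedRecall, object@weightedF1)
  if (any(!is.finite(sc)) || any(sc < 0) || any(sc > 1))
    msg <- c(msg, "scalar metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Heatmap: per-tile values on the spot's tile grid
#'
#' Values are min-max normalised to `[0, 1]` per spot. Grid cells with no
#' tile (discarded/empty tiles) are `NA`, never 0, so blanks are not confused
#' with low attention. A constant input map (zero range) yields all-zero
#' values and `constant = TRUE`.
#'
#' @slot values numeric R x C matrix on `[0, 1]`, `NA` for missing tiles.
#' @slot range the pre-normalisation `c(min, max)` of the placed values.
#' @slot constant TRUE when the un-normalised map had zero range.
#'
#' @seealso [attentionHeatmap()], [intensityHeatmap()], [discordanceMask()]
#' @exportClass Heatmap
setClass("Heatmap",
  representation(
    values = "matrix",
    range = "numeric",
    constant = "logical"
  )
)

setValidity("Heatmap", function(object) {
  msg <- character()
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "normalised values must lie in [0, 1]")
  if (length(object@range) != 2L)
    msg <- c(msg, "'range' must be length 2")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated, labelled spot collection
#'
#' @slot images list of [SpotImage-class] objects.
#' @slot labels data.frame with columns `spot_id`, `ihc_score`, `her2_status`
#'   and, for score-2 spots, `her2_signals`, `cen17_signals`.
#' @slot config generator configuration snapshot (list), including the seed.
#'
#' @seealso [generateCohort()]
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    images = "list",
    labels = "data.frame",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (length(object@images) != nrow(object@labels))
    msg <- c(msg, "one label row per image required")
  need <- c("spot_id", "ihc_score", "her2_status")
  if (!all(need %in% names(object@labels)))
    msg <- c(msg, "labels must contain spot_id, ihc_score, her2_status")
  if (length(msg)) msg else TRUE
})
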