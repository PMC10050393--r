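minMaxNormalise <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]))
    stop("no values to normalise")
  constant <- (rng[2] - rng[1]) < .Machine$double.eps
  vals <- if (constant) ifelse(is.na(v), NA_real_, 0)
  else (v - rng[1]) / (rng[2] - rng[1])
  list(values = vals, range = rng, constant = constant)
}

#' Attention heatmap on the tile grid
#'
#' Places the bag's attention weights on the spot's tile grid and min-max
#' normalises them to `[0, 1]` (per spot). Grid cells without a tile
#' (discarded/empty tiles) are `NA`, a reserved sentinel distinct from low
#' attention. A constant weight vector has zero range; it maps to all-zero
#' values with the `constant` flag set rather than producing NaN.
#'
#' @param weights attention weights aligned with `coords`.
#' @param coords `n x 2` matrix of 0-based `grid_row`, `grid_col`.
#' @param gridDim integer `c(rows, cols)` of the full tile grid.
#' @return a [Heatmap-class].
#' @export
attentionHeatmap <- function(weights, coords, gridDim) {
  coords <- rbind(coords)
  if (length(weights) != nrow(coords))
    stop("weights and coords must align")
  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key))
    stop("duplicate grid cell in coords")
  if (any(coords < 0) || any(coords[, 1] >= gridDim[1]) ||
      any(coords[, 2] >= gridDim[2]))
    stop("coords outside the tile grid")
  grid <- matrix(NA_real_, gridDim[1], gridDim[2])
  grid[cbind(coords[, 1] + 1L, coords[, 2] + 1L)] <- weights
  nm <- minMaxNormalise(grid)
  new("Heatmap", values = nm$values, range = nm$range,
      constant = nm$constant)
}

#' Patchwise mean staining-intensity heatmap
#'
#' Per-tile mean DAB concentration placed on the tile grid and min-max
#' normalised to `[0, 1]` — the intensity counterpart to the attention
#' heatmap, sharing its computation with [slideDescriptor()] (which takes
#' the maximum of exactly these per-tile means).
#'
#' @param bag a [TileBag-class].
#' @param profile a [StainProfile-class].
#' @return a [Heatmap-class].
#' @export
intensityHeatmap <- function(bag, profile = rjHDABProfile()) {
  stopifnot(is(bag, "TileBag"))
  if (nTiles(bag) == 0L)
    stop(sprintf("empty bag for spot '%s'", spotId(bag)))
  means <- vapply(bag@tiles, meanTileDAB, numeric(1), profile = profile)
  attentionHeatmap(means, tileCoords(bag), bag@gridDim)
}

#' 2-D embedding of tile embeddings
#'
#' Projects tile embeddings to two dimensions with t-SNE (delegated to the
#' Rtsne package — it is plumbing here, not a contribution), deterministic
#' given `seed`. The perplexity defaults to 30 and is automatically lowered
#' to the maximum valid value for small inputs.
#'
#' @param embeddings `n x d` matrix (`n >= 5`).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @return `n x 2` coordinate matrix.
#' @export
embed2d <- function(embeddings, seed = 1L, perplexity = 30) {
  embeddings <- rbind(embeddings)
  n <- nrow(embeddings)
  if (n < 5L) stop("need at least 5 points to embed")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  coords <- withSeed(deriveSeed(seed, "tsne"), {
    Rtsne::Rtsne(embeddings, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = n > 50, verbose = FALSE,
                 max_iter = 500)$Y
  })
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Attention / intensity discordance mask
#'
#' TRUE where the normalised attention and intensity heatmaps disagree by
#' more than `delta` — a computable rendering of "locations where the
#' attention values do not match staining intensity". Cells missing in
#' either map stay `NA`.
#'
#' @param attention,intensity [Heatmap-class] objects on the same grid.
#' @param delta disagreement threshold on the `[0, 1]` scale (default 0.5).
#' @return logical R x C matrix (with `NA` for missing cells).
#' @export
discordanceMask <- function(attention, intensity, delta = 0.5) {
  stopifnot(is(attention, "Heatmap"), is(intensity, "Heatmap"))
  a <- heatmapValues(attention)
  b <- heatmapValues(intensity)
  if (!all(dim(a) == dim(b)))
    stop("heatmap grids do not match")
  abs(a - b) > delta
}

#' Write a heatmap (and optional side-by-side panel) as PNG
#'
#' Renders the heatmap grid as a grayscale PNG, upsampling each grid cell
#' to `cellPx` pixels; missing cells render mid-grey with a darker border so
#' they are visually distinct from low values. `writeHeatmapPanel()` places
#' an attention and an intensity heatmap side by side.
#'
#' @param heatmap a [Heatmap-class].
#' @param path output PNG path.
#' @param cellPx pixels per grid cell (default 16).
#' @return invisibly `path`.
#' @export
writeHeatmapPNG <- function(heatmap, path, cellPx = 16L) {
  v <- heatmapValues(heatmap)
  img <- v[rep(seq_len(nrow(v)), each = cellPx),
           rep(seq_len(ncol(v)), each = cellPx)]
  img[is.na(img)] <- 0.5
  png::writePNG(img, path)
  invisible(path)
}

#' @param attention,intensity [Heatmap-class] objects.
#' @rdname writeHeatmapPNG
#' @export
writeHeatmapPanel <- function(attention, intensity, path, cellPx = 16L) {
  a <- heatmapValues(attention)
  b <- heatmapValues(intensity)
  stopifnot(all(dim(a) == dim(b)))
  gap <- matrix(1, nrow(a), 1)
  panel <- cbind(a, gap, b)
  img <- panel[rep(seq_len(nrow(panel)), each = cellPx),
               rep(seq_len(ncol(panel)), each = cellPx)]
  img[is.na(img)] <- 0.5
  png::writePNG(img, path)
  invisible(path)
}
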