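#' Construct a SpotImage
#'
#' Wraps a numeric `H x W x 3` array of 8-bit RGB intensities (values in
#' `[0, 255]`) as a [SpotImage-class].
#'
#' @param pixels `H x W x 3` numeric array on the `[0, 255]` scale, or on
#'   `[0, 1]` (auto-rescaled when the maximum is `<= 1`).
#' @param spotId spot identifier.
#' @param micronsPerPixel optional physical pixel size hint.
#' @return a [SpotImage-class].
#' @examples
#' img <- SpotImage(array(255, c(8, 8, 3)), "blank")
#' dim(pixels(img))
#' @export
SpotImage <- function(pixels, spotId = "spot", micronsPerPixel = NA_real_) {
  pixels <- unname(pixels)
  if (length(dim(pixels)) == 2L)  # grey input: replicate to 3 channels
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (max(pixels) <= 1 && min(pixels) >= 0)
    pixels <- pixels * 255
  storage.mode(pixels) <- "double"
  new("SpotImage", pixels = pixels, spotId = as.character(spotId),
      micronsPerPixel = as.numeric(micronsPerPixel))
}

#' Read / write spot images
#'
#' Reads an RGB spot image from PNG or JPEG (selected by file extension) and
#' returns a [SpotImage-class] on the `[0, 255]` scale. TIFF input is not
#' supported (no TIFF reader is available); convert to PNG first.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @param spotId identifier; defaults to the file name without extension.
#' @return [SpotImage-class] (`readSpotImage`); invisibly `path`
#'   (`writeSpotImage`).
#' @export
readSpotImage <- function(path, spotId = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: '.", ext, "' (use PNG or JPEG)")
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] > 3L)
    raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  SpotImage(raw * 255,
            spotId %||% tools::file_path_sans_ext(basename(path)))
}

#' @param image a [SpotImage-class].
#' @rdname readSpotImage
#' @export
writeSpotImage <- function(image, path) {
  stopifnot(is(image, "SpotImage"))
  ext <- tolower(tools::file_ext(path))
  arr <- pixels(image) / 255
  switch(ext,
    png  = png::writePNG(arr, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(arr, path, quality = 0.95),
    stop("unsupported image format: '.", ext, "'")
  )
  invisible(path)
}

#' Tile-grid dimensions of an image
#'
#' Number of complete, non-overlapping tiles along each image axis:
#' `floor(H / tileSize)` by `floor(W / tileSize)`. Remainder pixels at the
#' right/bottom edges are dropped, not padded.
#'
#' @param h,w image height and width in pixels.
#' @param tileSize tile side length in pixels.
#' @return integer `c(rows, cols)`.
#' @examples
#' tileGrid(5468, 5468, 224)  # 24 x 24 -> 576 candidate tiles
#' @export
tileGrid <- function(h, w, tileSize = 224L) {
  stopifnot(tileSize >= 1)
  c(rows = as.integer(h %/% tileSize), cols = as.integer(w %/% tileSize))
}

#' Is a tile empty (background)?
#'
#' A tile is empty when fewer than `tissueFraction` of its pixels carry
#' tissue, where a pixel carries tissue when its optical density summed over
#' the RGB channels exceeds `odThreshold`. An all-black tile has maximal OD
#' and is therefore *not* empty by this rule; it is flagged with a message as
#' a likely scanner artefact so it reaches QA rather than silently vanishing.
#'
#' @param tile a `ts x ts x 3` pixel array on `[0, 255]`.
#' @param odThreshold summed-OD threshold for a pixel to count as tissue
#'   (default 0.15, mirroring the Macenko transparency cut).
#' @param tissueFraction minimum tissue-pixel fraction of a non-empty tile.
#' @return logical scalar.
#' @export
isEmptyTile <- function(tile, odThreshold = 0.15, tissueFraction = 0.10) {
  stopifnot(odThreshold > 0, tissueFraction > 0, tissueFraction < 1)
  od <- rgbToOD(tile)
  odSum <- od[, , 1] + od[, , 2] + od[, , 3]
  if (max(tile) < 1)
    message("all-black tile encountered (possible scanner artefact); ",
            "kept as non-empty")
  mean(odSum > odThreshold) < tissueFraction
}

#' Cut a spot image into a bag of tiles
#'
#' Extracts non-overlapping `tileSize x tileSize` tiles in row-major order
#' (the stable order attention maps rely on). Right/bottom remainder pixels
#' are dropped. With `discardEmpty = TRUE`, tiles failing the
#' [isEmptyTile()] criterion are removed from the bag (their grid cells stay
#' empty); if every tile is empty an error naming the spot is raised.
#'
#' @param image a [SpotImage-class].
#' @param tileSize tile side in pixels (default 224).
#' @param discardEmpty drop background tiles?
#' @param odThreshold,tissueFraction forwarded to [isEmptyTile()].
#' @return a [TileBag-class].
#' @examples
#' img <- SpotImage(array(runif(96 * 96 * 3, 0, 255), c(96, 96, 3)), "s1")
#' nTiles(tileImage(img, tileSize = 32, discardEmpty = FALSE))  # 9
#' @export
tileImage <- function(image, tileSize = 224L, discardEmpty = FALSE,
                      odThreshold = 0.15, tissueFraction = 0.10) {
  stopifnot(is(image, "SpotImage"))
  px <- pixels(image)
  d <- dim(px)
  tileSize <- as.integer(tileSize)
  if (d[1] < tileSize || d[2] < tileSize)
    stop(sprintf("image '%s' (%d x %d) is smaller than the tile size %d",
                 spotId(image), d[1], d[2], tileSize))
  grid <- tileGrid(d[1], d[2], tileSize)
  tiles <- vector("list", grid[1] * grid[2])
  coords <- matrix(0L, grid[1] * grid[2], 2L,
                   dimnames = list(NULL, c("grid_row", "grid_col")))
  k <- 0L
  for (r in seq_len(grid[1]) - 1L) {        # row-major: rows outer
    rows <- (r * tileSize + 1L):((r + 1L) * tileSize)
    for (cc in seq_len(grid[2]) - 1L) {
      cols <- (cc * tileSize + 1L):((cc + 1L) * tileSize)
      k <- k + 1L
      tiles[[k]] <- px[rows, cols, , drop = FALSE]
      coords[k, ] <- c(r, cc)
    }
  }
  if (discardEmpty) {
    keep <- !vapply(tiles, isEmptyTile, logical(1),
                    odThreshold = odThreshold,
                    tissueFraction = tissueFraction)
    if (!any(keep))
      stop(sprintf("all tiles of spot '%s' are empty", spotId(image)))
    tiles <- tiles[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  new("TileBag", tiles = tiles, coords = coords, spotId = spotId(image),
      tileSize = tileSize, gridDim = unname(grid))
}

#' Reassemble a full bag back into an image array
#'
#' Inverse of [tileImage()] without discard: pastes the tiles back on their
#' grid, reproducing the top-left `rows*ts x cols*ts` part of the original
#' image bit-exactly. Missing grid cells are filled with white (255).
#'
#' @param bag a [TileBag-class].
#' @return numeric pixel array.
#' @export
reassembleTiles <- function(bag) {
  stopifnot(is(bag, "TileBag"))
  ts <- bag@tileSize
  out <- array(255, c(bag@gridDim[1] * ts, bag@gridDim[2] * ts, 3L))
  for (k in seq_along(bag@tiles)) {
    r <- bag@coords[k, 1]; cc <- bag@coords[k, 2]
    out[(r * ts + 1):((r + 1) * ts), (cc * ts + 1):((cc + 1) * ts), ] <-
      bag@tiles[[k]]
  }
  out
}

#' Linear downscale factor
#'
#' The reported linear scale factor of a square downscale, rounded to two
#' decimals (5468 -> 1024 gives 5.34).
#'
#' @param side source side in pixels.
#' @param targetSide target side in pixels.
#' @return numeric scalar.
#' @examples
#' downscaleFactor(5468, 1024)
#' @export
downscaleFactor <- function(side, targetSide) round(side / targetSide, 2)

# Separable area-average resampling matrix: target pixel i covers the source
# interval [i*s, (i+1)*s), s = src/dst; weights are interval overlaps.
resampleWeights <- function(src, dst) {
  s <- src / dst
  lo <- (seq_len(dst) - 1) * s
  hi <- seq_len(dst) * s
  j0 <- seq_len(src) - 1
  W <- outer(hi, j0 + 1, pmin) - outer(lo, j0, pmax)
  pmax(W, 0) / s
}

#' Downscale a square spot image
#'
#' Anti-aliased resampling of a square spot to `targetSide x targetSide`.
#' The default `"area"` method averages each target pixel over the exact
#' source area it covers; `"bilinear"` interpolates at target pixel centres.
#' The linear scale factor (`side / targetSide`, rounded to 2 decimals) is
#' stored in the result's `metadata$scaleFactor`.
#'
#' @param image a square [SpotImage-class].
#' @param targetSide target side length (default 1024).
#' @param method `"area"` (default) or `"bilinear"`.
#' @return downscaled [SpotImage-class].
#' @export
downscaleImage <- function(image, targetSide = 1024L,
                           method = c("area", "bilinear")) {
  stopifnot(is(image, "SpotImage"))
  method <- match.arg(method)
  px <- pixels(image)
  d <- dim(px)
  if (d[1] != d[2])
    stop("downscaleImage expects a square image (spots are square)")
  side <- d[1]
  targetSide <- as.integer(targetSide)
  if (side == targetSide) {
    out <- image
    out@metadata$scaleFactor <- 1.00
    return(out)
  }
  res <- array(0, c(targetSide, targetSide, 3L))
  if (method == "area") {
    W <- resampleWeights(side, targetSide)
    for (ch in 1:3) res[, , ch] <- W %*% px[, , ch] %*% t(W)
  } else {
    # bilinear at target pixel centres
    s <- side / targetSide
    pos <- (seq_len(targetSide) - 0.5) * s + 0.5 - 0.5  # source coordinate
    pos <- pmin(pmax(pos, 1), side)
    i0 <- pmin(floor(pos), side - 1)
    fr <- pos - i0
    for (ch in 1:3) {
      X <- px[, , ch]
      rows <- X[i0, , drop = FALSE] * (1 - fr) + X[i0 + 1, , drop = FALSE] * fr
      res[, , ch] <- rows[, i0, drop = FALSE] * rep(1 - fr, each = targetSide) +
        rows[, i0 + 1, drop = FALSE] * rep(fr, each = targetSide)
    }
  }
  res <- pmin(pmax(res, 0), 255)
  out <- SpotImage(res, spotId(image), image@micronsPerPixel)
  out@metadata <- image@metadata
  out@metadata$scaleFactor <- downscaleFactor(side, targetSide)
  out
}

#' Flip helpers
#'
#' `flipLR()` mirrors an image array left-right, `flipUD()` top-bottom.
#' Both accept `H x W x 3` arrays (or matrices) and preserve shape.
#'
#' @param x pixel array.
#' @return flipped array of the same shape.
#' @export
flipLR <- function(x) {
  if (length(dim(x)) == 3L) x[, dim(x)[2]:1, , drop = FALSE]
  else x[, ncol(x):1, drop = FALSE]
}

#' @rdname flipLR
#' @export
flipUD <- function(x) {
  if (length(dim(x)) == 3L) x[dim(x)[1]:1, , , drop = FALSE]
  else x[nrow(x):1, , drop = FALSE]
}
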