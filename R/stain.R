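#' RGB to optical density (Beer-Lambert)
#'
#' Per channel, `od = -log10(max(I, 1) / i0)`. Intensities are clipped to
#' `>= 1` before the logarithm so black pixels give a finite maximal OD of
#' `log10(i0)` (about 2.407 for `i0 = 255`). Base-10 logarithms follow the
#' Ruifrok-Johnston convention; `base = exp(1)` switches to natural logs for
#' comparison with codebases that use them.
#'
#' @param x a [SpotImage-class] or a numeric pixel array on `[0, 255]`.
#' @param i0 reference white intensity (default 255).
#' @param base logarithm base (default 10).
#' @return numeric array of the same shape, values `>= 0`.
#' @examples
#' rgbToOD(array(25.5, c(1, 1, 3)))  # 1 in every channel
#' @export
rgbToOD <- function(x, i0 = 255, base = 10) {
  stopifnot(i0 > 0)
  px <- if (is(x, "SpotImage")) pixels(x) else x
  -log(pmax(px, 1) / i0, base = base)
}

#' Optical density back to RGB
#'
#' Inverse of [rgbToOD()]: `I = i0 * base^(-od)`, clipped to `[0, 255]`.
#'
#' @param od numeric OD array.
#' @inheritParams rgbToOD
#' @return pixel array on `[0, 255]`.
#' @export
odToRGB <- function(od, i0 = 255, base = 10) {
  pmin(pmax(i0 * base^(-od), 0), 255)
}

#' Construct a StainProfile
#'
#' @param stainMatrix 3x3 matrix whose rows are OD vectors for hematoxylin,
#'   DAB and residual; rows are normalised to unit length.
#' @param maxConcentrations robust per-stain maxima (hematoxylin, DAB).
#' @return a [StainProfile-class].
#' @export
StainProfile <- function(stainMatrix, maxConcentrations = c(1, 1)) {
  M <- stainMatrix / sqrt(rowSums(stainMatrix^2))
  new("StainProfile", stainMatrix = unname(M),
      maxConcentrations = as.numeric(maxConcentrations))
}

#' The Ruifrok-Johnston H-DAB profile
#'
#' The published hematoxylin and DAB optical-density vectors, with a residual
#' third row completing the basis (unit cross product). This fixed profile is
#' the fallback whenever Macenko estimation fails or is disabled.
#'
#' @param maxConcentrations robust maxima to attach (default `c(1, 1)`).
#' @return a [StainProfile-class].
#' @export
rjHDABProfile <- function(maxConcentrations = c(1, 1)) {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  StainProfile(rbind(h, d, r / sqrt(sum(r^2))), maxConcentrations)
}

# flatten H x W x 3 <-> N x 3
odToRows <- function(od) {
  d <- dim(od)
  matrix(od, d[1] * d[2], 3L)
}

rowsToOD <- function(rows, d) array(rows, d)

#' Colour deconvolution
#'
#' Unmixes a per-pixel OD image into per-stain concentrations: for each pixel
#' the concentrations `c` solve `t(M) %*% c = od` with `M` the stain matrix
#' (least squares via the QR decomposition when the system is
#' ill-conditioned). Negative concentrations are retained, not clipped;
#' pass `clip = TRUE` to clip explicitly.
#'
#' @param od OD array (`H x W x 3`), e.g. from [rgbToOD()].
#' @param profile a [StainProfile-class].
#' @param clip clip negative concentrations to zero?
#' @return concentration array `H x W x 3` (planes: hematoxylin, DAB,
#'   residual, matching the profile rows).
#' @seealso [convolveStains()] for the inverse.
#' @export
deconvolveStains <- function(od, profile, clip = FALSE) {
  stopifnot(is(profile, "StainProfile"))
  M <- stainMatrix(profile)
  if (abs(det(M)) < 1e-8) stop("singular stain matrix")
  # od_row = c_row %*% M  =>  c_row = od_row %*% solve(M)
  inv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(inv)) inv <- qr.solve(M)  # least-squares fallback
  d <- dim(od)
  conc <- rowsToOD(odToRows(od) %*% inv, d)
  if (clip) conc <- pmax(conc, 0)
  conc
}

#' Stain convolution (re-mixing)
#'
#' Inverse of [deconvolveStains()]: maps per-stain concentrations back to an
#' OD image, `od_row = c_row %*% M`.
#'
#' @param conc concentration array `H x W x 3`.
#' @param profile a [StainProfile-class].
#' @return OD array.
#' @export
convolveStains <- function(conc, profile) {
  stopifnot(is(profile, "StainProfile"))
  d <- dim(conc)
  rowsToOD(odToRows(conc) %*% stainMatrix(profile), d)
}

#' Macenko stain estimation
#'
#' Estimates the two dominant stain vectors of an H-DAB image from its
#' optical-density cloud: transparent pixels (summed OD below `beta`) are
#' removed, the two principal OD directions are found by SVD, every tissue
#' pixel is expressed as an angle in that plane, and the extreme
#' (`alphaPercentile` / `100 - alphaPercentile`) directions are returned as
#' the stain rows. The row with the *smaller* blue-channel OD is hematoxylin
#' (a blue stain transmits blue light, so it absorbs little of it; DAB is
#' brown and absorbs blue strongly). A unit cross product completes the
#' basis, and robust (99th percentile) hematoxylin/DAB concentrations are
#' attached for later normalization.
#'
#' @param image a [SpotImage-class] (or pixel array).
#' @param alphaPercentile angle percentile for the extreme directions
#'   (default 1).
#' @param beta transparency cut on summed OD (default 0.15).
#' @param minTissue minimum number of tissue pixels required (default 100).
#' @return a [StainProfile-class].
#' @export
macenkoEstimate <- function(image, alphaPercentile = 1.0, beta = 0.15,
                            minTissue = 100L) {
  od <- rgbToOD(image)
  rows <- odToRows(od)
  tissue <- rows[rowSums(rows) > beta, , drop = FALSE]
  if (nrow(tissue) < minTissue)
    stop(sprintf(
      "degenerate input: only %d pixels above the transparency cut (need %d)",
      nrow(tissue), minTissue))
  sv <- svd(tissue, nu = 0, nv = 2)
  if (sv$d[2] < 1e-3 * sv$d[1])
    stop("rank-1 OD cloud (single stain); use a fixed fallback profile ",
         "such as rjHDABProfile()")
  V <- sv$v                                   # 3 x 2 principal plane
  # orient basis vectors so projections are mostly positive
  proj <- tissue %*% V
  for (j in 1:2) if (sum(proj[, j]) < 0) { V[, j] <- -V[, j]; proj[, j] <- -proj[, j] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(alphaPercentile, 100 - alphaPercentile) / 100,
                        names = FALSE)
  v1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  if (sum(v1 < 0) > 1) v1 <- -v1  # stain OD vectors are non-negative
  if (sum(v2 < 0) > 1) v2 <- -v2
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  # hematoxylin = smaller blue-channel OD
  if (v1[3] <= v2[3]) { h <- v1; dab <- v2 } else { h <- v2; dab <- v1 }
  r <- c(h[2] * dab[3] - h[3] * dab[2],
         h[3] * dab[1] - h[1] * dab[3],
         h[1] * dab[2] - h[2] * dab[1])
  prof <- StainProfile(rbind(c(h), c(dab), r / sqrt(sum(r^2))))
  conc <- tissue %*% solve(stainMatrix(prof))
  mx <- apply(conc[, 1:2, drop = FALSE], 2,
              stats::quantile, probs = 0.99, names = FALSE)
  prof@maxConcentrations <- pmax(as.numeric(mx), 1e-6)
  prof
}

#' Stain normalization by deconvolution/convolution
#'
#' Matches the staining of `image` (described by `source`) to a `target`
#' profile: deconvolve with the source matrix, rescale the hematoxylin and
#' DAB concentrations by the ratio of the robust maxima
#' (`target / source`), re-mix with the target matrix, and map back to RGB
#' (clipped to `[0, 255]`). The residual channel passes through unscaled, so
#' `source == target` is an identity up to the 8-bit round trip.
#'
#' @param image a [SpotImage-class].
#' @param source [StainProfile-class] describing the image's own staining
#'   (e.g. from [macenkoEstimate()]).
#' @param target [StainProfile-class] of the reference cohort.
#' @return normalized [SpotImage-class].
#' @export
normalizeStains <- function(image, source, target) {
  stopifnot(is(image, "SpotImage"),
            is(source, "StainProfile"), is(target, "StainProfile"))
  conc <- deconvolveStains(rgbToOD(image), source)
  scale <- maxConcentrations(target) / maxConcentrations(source)
  conc[, , 1] <- conc[, , 1] * scale[1]
  conc[, , 2] <- conc[, , 2] * scale[2]
  rgb <- odToRGB(convolveStains(conc, target))
  out <- SpotImage(rgb, spotId(image), image@micronsPerPixel)
  out@metadata <- image@metadata
  out
}

#' Mean DAB concentration of a tile
#'
#' Average of the DAB concentration plane (second stain row) over all tile
#' pixels after colour deconvolution — the per-tile staining intensity used
#' by the intensity baseline and the intensity heatmaps.
#'
#' @param tile `ts x ts x 3` pixel array on `[0, 255]`.
#' @param profile a [StainProfile-class] (default the fixed H-DAB profile).
#' @return numeric scalar.
#' @export
meanTileDAB <- function(tile, profile = rjHDABProfile()) {
  conc <- deconvolveStains(rgbToOD(tile), profile)
  mean(conc[, , 2])
}

#' Serialise / read a stain profile as JSON
#'
#' Profiles are tiny (nine matrix entries plus two maxima) and travel as
#' plain JSON files.
#'
#' @param profile a [StainProfile-class].
#' @param path output / input file path.
#' @return invisibly `path` (write); a [StainProfile-class] (read).
#' @export
writeStainProfile <- function(profile, path) {
  stopifnot(is(profile, "StainProfile"))
  jsonlite::write_json(
    list(stain_matrix = stainMatrix(profile),
         max_concentrations = maxConcentrations(profile)),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeStainProfile
#' @export
readStainProfile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  StainProfile(matrix(unlist(x$stain_matrix), 3, 3),
               as.numeric(x$max_concentrations))
}
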