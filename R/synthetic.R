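#' Synthetic spot specification
#'
#' Parameters of one generated IHC spot. The generator emulates the three
#' scoring factors of HER2 IHC: staining intensity (`dabPeakOD`), the extent
#' of connected positive cells, and the cellular location of the staining
#' (`membraneCompleteness`, the rendered arc fraction of each cell's
#' membranous ring). In the `intensity_coded` regime DAB peak OD and
#' completeness both increase with score (with a score-2-positive spot
#' stained more strongly than a score-2-negative one) and each stained spot
#' carries one confluent high-coverage cluster, so the slide descriptor
#' recovers the peak OD. In the `morphology_only` regime score-2-positive
#' and score-2-negative spots share the same `dabPeakOD` distribution and
#' the same stained area, ring radius and thickness; positives render one
#' contiguous membranous arc per cell while negatives render the same total
#' arc length split into six fragments (discontinuous membranous staining),
#' so the intensity descriptor carries no status signal by construction and
#' only the staining *pattern* (connectivity) separates the classes.
#'
#' @param score IHC score in `{0, 1, 2, 3}`.
#' @param status HER2 status in `{0, 1}`; must be consistent with the score
#'   (score 0/1 negative, 3 positive; score 2 either). Defaults to the
#'   score-determined status, which is required for score 2.
#' @param regime `"intensity_coded"` or `"morphology_only"`.
#' @param sidePx spot side in pixels; must be a multiple of `tileSize`
#'   (desk default 192 = 6 x 6 tiles of 32 px).
#' @param tileSize tile side the spot is meant to be cut into.
#' @param cellDensity expected cells per tile (default 3).
#' @param membraneCompleteness arc fraction in `[0, 1]`; `NULL` picks the
#'   regime/score default.
#' @param dabPeakOD peak DAB optical density; `NULL` picks the regime/score
#'   default.
#' @param noiseSd per-channel Gaussian OD noise (default 0.02).
#' @param seed spot RNG seed.
#' @return a list of class `syntheticSpotSpec`.
#' @export
syntheticSpotSpec <- function(score, status = NULL,
                              regime = c("intensity_coded", "morphology_only"),
                              sidePx = 192L, tileSize = 32L,
                              cellDensity = 3, membraneCompleteness = NULL,
                              dabPeakOD = NULL, noiseSd = 0.02, seed = 1L) {
  regime <- match.arg(regime)
  if (!score %in% 0:3) stop("score must be in {0, 1, 2, 3}")
  if (is.null(status)) {
    if (score == 2)
      stop("score-2 spots need an explicit status")
    status <- scoreToStatus(score)
  }
  if (!status %in% 0:1) stop("status must be 0 or 1")
  if (score %in% c(0, 1) && status != 0)
    stop(sprintf("inconsistent labels: score %d implies negative status",
                 score))
  if (score == 3 && status != 1)
    stop("inconsistent labels: score 3 implies positive status")
  if (sidePx %% tileSize != 0)
    stop("sidePx must be a multiple of tileSize")
  def <- defaultStainParams(score, status, regime)
  spec <- list(score = as.integer(score), status = as.integer(status),
               regime = regime, sidePx = as.integer(sidePx),
               tileSize = as.integer(tileSize), cellDensity = cellDensity,
               membraneCompleteness = membraneCompleteness %||% def$completeness,
               dabPeakOD = dabPeakOD %||% def$peak,
               membraneFragments = def$fragments,
               noiseSd = noiseSd, seed = as.integer(seed))
  if (spec$membraneCompleteness < 0 || spec$membraneCompleteness > 1)
    stop("membraneCompleteness must lie in [0, 1]")
  if (spec$dabPeakOD < 0) stop("dabPeakOD must be non-negative")
  class(spec) <- "syntheticSpotSpec"
  spec
}

# regime/score default staining parameters: peak DAB OD, arc completeness
# and the number of membrane fragments the arc is split into. In the
# morphology-only regime both statuses share peak, completeness and
# thickness (so the intensity descriptor is status-blind by symmetry);
# positives render one contiguous arc, negatives the same total arc length
# split into 6 fragments (discontinuous membranous staining).
defaultStainParams <- function(score, status, regime) {
  if (regime == "morphology_only")
    return(list(peak = 0.7, completeness = 0.9,
                fragments = if (status == 1) 1L else 6L))
  key <- if (score == 2) paste0("2", if (status == 1) "+" else "-")
  else as.character(score)
  peaks <- c("0" = 0, "1" = 0.35, "2-" = 0.55, "2+" = 0.85, "3" = 1.2)
  comp <- c("0" = 0, "1" = 0.30, "2-" = 0.50, "2+" = 0.70, "3" = 0.90)
  list(peak = unname(peaks[key]), completeness = unname(comp[key]),
       fragments = 1L)
}

#' Generate one synthetic spot
#'
#' Renders a circular tissue disc on a white background: hematoxylin-toned
#' nuclei scattered over a faint counterstain haze, DAB staining per the
#' spec's regime (membranous arcs — contiguous or fragmented — and, in the
#' intensity-coded regime, one confluent cluster whose tile-mean DAB
#' recovers the peak OD), composed through Beer-Lambert with the fixed
#' H-DAB profile, plus per-channel Gaussian OD noise and mild vignetting.
#' Deterministic: the same spec (including its seed) yields a bit-identical
#' image.
#'
#' @param spec a [syntheticSpotSpec()].
#' @param spotId identifier for the generated spot.
#' @return list with `image` (a [SpotImage-class]) and `label` (one-row
#'   data.frame with `spot_id`, `ihc_score`, `her2_status`, and ISH counts
#'   for score-2 spots).
#' @export
generateSpot <- function(spec, spotId = sprintf("synthetic_%d", spec$seed)) {
  stopifnot(inherits(spec, "syntheticSpotSpec"))
  s <- spec$sidePx
  withSeed(spec$seed, {
    rows <- matrix(seq_len(s), s, s)
    cols <- matrix(seq_len(s), s, s, byrow = TRUE)
    ctr <- (s + 1) / 2
    tissueR <- 0.46 * s
    distCtr <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
    tissue <- distCtr <= tissueR
    cH <- matrix(0, s, s)
    cD <- matrix(0, s, s)
    cH[tissue] <- 0.12                       # counterstain haze
    nTilesSide <- s %/% spec$tileSize
    nCells <- round(spec$cellDensity * nTilesSide^2)
    u <- stats::runif(nCells)
    rad <- 0.92 * tissueR * sqrt(u)
    ang <- stats::runif(nCells, 0, 2 * pi)
    cx <- ctr + rad * cos(ang)
    cy <- ctr + rad * sin(ang)
    cr <- stats::runif(nCells, 4.5, 6.5)
    nFrag <- spec$membraneFragments %||% 1L
    for (k in seq_len(nCells)) {
      r <- cr[k]
      win <- ceiling(r + 4)
      i0 <- max(1, floor(cx[k]) - win); i1 <- min(s, floor(cx[k]) + win)
      j0 <- max(1, floor(cy[k]) - win); j1 <- min(s, floor(cy[k]) + win)
      ii <- i0:i1; jj <- j0:j1
      dx <- outer(ii - cx[k], rep(1, length(jj)))
      dy <- outer(rep(1, length(ii)), jj - cy[k])
      dist <- sqrt(dx^2 + dy^2)
      # nucleus (hematoxylin)
      nuc <- 0.7 * exp(-dist^2 / (2 * (0.45 * r)^2))
      cH[ii, jj] <- pmax(cH[ii, jj], nuc)
      if (spec$dabPeakOD > 0) {
        # membranous staining: total arc fraction `completeness`, split into
        # nFrag fragments placed at a random offset within equal sectors —
        # identical mass and thickness for any nFrag, so fragmentation
        # changes the pattern but not the intensity descriptor
        theta <- (atan2(dy, dx)) %% (2 * pi)
        fragLen <- 2 * pi * spec$membraneCompleteness / nFrag
        sector <- 2 * pi / nFrag
        phase <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(1, 0, sector - fragLen)
        rel <- (theta - phase) %% (2 * pi)
        inSector <- rel %% sector
        arc <- inSector >= off & inSector <= off + fragLen
        contrib <- spec$dabPeakOD * exp(-(dist - r)^2) * arc
        cD[ii, jj] <- pmax(cD[ii, jj], contrib)
      }
    }
    # confluent cluster: one tile-sized region of near-total DAB coverage
    if (spec$regime == "intensity_coded" && spec$dabPeakOD > 0) {
      ts <- spec$tileSize
      inner <- if (nTilesSide >= 3L) seq(2L, nTilesSide - 1L)
      else seq_len(nTilesSide)
      tr <- inner[sample.int(length(inner), 1)]
      tc <- inner[sample.int(length(inner), 1)]
      hx <- (tr - 1) * ts + (ts + 1) / 2
      hy <- (tc - 1) * ts + (ts + 1) / 2
      hr <- 0.75 * ts
      dist <- sqrt((rows - hx)^2 + (cols - hy)^2)
      hot <- spec$dabPeakOD * pmin(1, pmax(0, (hr - dist) / 3))
      cD <- pmax(cD, hot)
      cH <- pmax(cH, 0.3 * (dist < hr))
    }
    M <- stainMatrix(rjHDABProfile())
    od <- array(0, c(s, s, 3))
    for (ch in 1:3)
      od[, , ch] <- cH * M[1, ch] + cD * M[2, ch] +
        0.03 * (distCtr / (s / 2))^2 * tissue +        # mild vignetting
        stats::rnorm(s * s, sd = spec$noiseSd)
    img <- SpotImage(round(odToRGB(od)), spotId)
    label <- data.frame(spot_id = spotId, ihc_score = spec$score,
                        her2_status = spec$status,
                        her2_signals = NA_real_, cen17_signals = NA_real_)
    if (spec$score == 2) {
      ish <- generateIshCounts(spec$status)
      label$her2_signals <- ish[1]
      label$cen17_signals <- ish[2]
    }
    list(image = img, label = label)
  })
}

#' Simulated ISH signal counts
#'
#' Draws (HER2, CEN17) mean signal counts whose [ishCall()] reproduces the
#' requested status by construction: positives draw either a ratio in
#' `[2.2, 8]` or an absolute HER2 count in `[6.5, 12]`; negatives draw a
#' ratio in `[0.8, 1.8]` with HER2 below 6.
#'
#' @param status target HER2 status (0/1).
#' @return numeric `c(her2_signals, cen17_signals)`.
#' @export
generateIshCounts <- function(status) {
  stopifnot(status %in% 0:1)
  if (status == 1) {
    if (stats::runif(1) < 0.5) {
      cen <- stats::runif(1, 1.5, 3)
      her2 <- stats::runif(1, 2.2, 8) * cen
    } else {
      her2 <- stats::runif(1, 6.5, 12)
      cen <- stats::runif(1, 2.5, 5)
    }
  } else {
    cen <- stats::runif(1, 1.5, 3)
    her2 <- stats::runif(1, 0.8, 1.8) * cen
  }
  c(her2_signals = her2, cen17_signals = cen)
}

# largest-remainder apportionment of n into length(props) integer counts
apportion <- function(n, props) {
  q <- n * props / sum(props)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic cohort
#'
#' Builds `n` spots with IHC-score counts apportioned to
#' `classProportions` (largest-remainder rule; the default mirrors the
#' 416/186/14/37 score distribution of a 653-sample external cohort).
#' Score-2 spots are assigned positive status with probability
#' `score2PosFrac` (exact counts, not draws) and receive simulated ISH
#' counts consistent with their status. In the `morphology_only` regime the
#' default proportions put every spot at score 2 with a 50/50 status split.
#' Fully deterministic given `seed`.
#'
#' @param n cohort size.
#' @param classProportions length-4 score proportions (scores 0-3);
#'   `NULL` uses the regime default.
#' @param regime `"intensity_coded"` or `"morphology_only"`.
#' @param seed master seed.
#' @param sidePx,tileSize,cellDensity,noiseSd forwarded to
#'   [syntheticSpotSpec()].
#' @param score2PosFrac fraction of score-2 spots with positive status.
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(n, classProportions = NULL,
                           regime = c("intensity_coded", "morphology_only"),
                           seed = 1L, sidePx = 192L, tileSize = 32L,
                           cellDensity = 3, noiseSd = 0.02,
                           score2PosFrac = 0.5) {
  regime <- match.arg(regime)
  classProportions <- classProportions %||%
    if (regime == "morphology_only") c(0, 0, 1, 0)
    else c(416, 186, 14, 37) / 653
  if (abs(sum(classProportions) - 1) > 1e-6)
    stop("classProportions must sum to 1")
  counts <- apportion(n, classProportions)
  if (n < sum(classProportions > 0))
    stop("n too small for the requested strata")
  scores <- rep(0:3, counts)
  status <- integer(n)
  status[scores %in% c(0, 1)] <- 0L
  status[scores == 3] <- 1L
  i2 <- which(scores == 2)
  nPos <- round(score2PosFrac * length(i2))
  status[i2] <- rep(c(1L, 0L), c(nPos, length(i2) - nPos))
  jitter <- withSeed(deriveSeed(seed, "generator"),
                     stats::runif(n, 0.85, 1.15))
  spots <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- syntheticSpotSpec(
      score = scores[i], status = status[i], regime = regime,
      sidePx = sidePx, tileSize = tileSize, cellDensity = cellDensity,
      noiseSd = noiseSd, seed = deriveSeed(seed, 100L + i))
    spec$dabPeakOD <- spec$dabPeakOD * jitter[i]
    sp <- generateSpot(spec, spotId = sprintf("spot_%04d", i))
    spots[[i]] <- sp$image
    labels[[i]] <- sp$label
  }
  new("SyntheticCohort",
      images = spots,
      labels = do.call(rbind, labels),
      config = list(n = n, classProportions = classProportions,
                    regime = regime, seed = seed, sidePx = sidePx,
                    tileSize = tileSize, cellDensity = cellDensity,
                    noiseSd = noiseSd, score2PosFrac = score2PosFrac))
}

#' Write a cohort to disk
#'
#' Writes one PNG per spot, a `labels.csv` in the training schema
#' (`spot_id`, `ihc_score`, `her2_status`, `her2_signals`,
#' `cen17_signals`) and a `config.json` generator snapshot.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly `dir`.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in cohort@images)
    writeSpotImage(img, file.path(dir, paste0(spotId(img), ".png")))
  utils::write.csv(cohort@labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labels table
#'
#' Reads and validates the labels CSV schema used across the package:
#' `spot_id`, `ihc_score`, `her2_status` plus optional `her2_signals`,
#' `cen17_signals`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "ihc_score", "her2_status")
  if (!all(need %in% names(df)))
    stop("labels file must contain columns: ", paste(need, collapse = ", "))
  if (!all(df$ihc_score %in% 0:3))
    stop("invalid IHC score value(s) in labels file")
  if (!all(df$her2_status %in% 0:1))
    stop("invalid HER2 status value(s) in labels file")
  df
}
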