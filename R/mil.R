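#' Attention weights over a bag of embeddings
#'
#' The un-gated attention operator: for tile embeddings `h_k` the raw score
#' is `s_k = w' tanh(V h_k)` and the weight is the softmax
#' `a_k = exp(s_k) / sum_j exp(s_j)`, computed with max subtraction for
#' numerical stability. Weights are non-negative and sum to one, so the
#' pooled bag representation is invariant to bag size. A gated variant
#' (`gated = TRUE`, with parameters `U`) multiplies `tanh(V h)` elementwise
#' by `sigmoid(U h)` before the dot product.
#'
#' @param H `n x d` matrix of tile embeddings (rows = tiles).
#' @param params list with `V` (`L x d`), `w` (length `L`), and optionally
#'   `U` (`L x d`) for the gated variant.
#' @param gated use the gated attention variant?
#' @return numeric vector of `n` weights summing to 1.
#' @examples
#' p <- list(V = matrix(c(1, 0), 1, 2), w = 1)
#' attentionScores(rbind(c(0, 0), c(10, 0)), p)
#' @export
attentionScores <- function(H, params, gated = FALSE) {
  H <- rbind(H)
  n <- nrow(H)
  if (n == 0L) stop("empty bag: no embeddings to attend over")
  A <- tanh(H %*% t(params$V))                 # n x L
  if (gated) {
    if (is.null(params$U)) stop("gated attention requires params$U")
    A <- A * stats::plogis(H %*% t(params$U))
  }
  s <- drop(A %*% params$w)
  assertFinite(s, "attention scores")
  e <- exp(s - max(s))
  e / sum(e)
}

#' Attention-weighted bag aggregation
#'
#' The bag representation is the weighted sum `z = sum_k a_k h_k`. Because
#' the weights sum to one, permuting the tiles or duplicating every tile
#' leaves `z` unchanged.
#'
#' @param H `n x d` embeddings.
#' @param weights `n` attention weights (from [attentionScores()]).
#' @return list with `z` (length-`d` vector) and `attention` (the weights).
#' @export
aggregateBag <- function(H, weights) {
  H <- rbind(H)
  if (nrow(H) != length(weights))
    stop("length mismatch between embeddings and weights")
  list(z = drop(crossprod(H, weights)), attention = weights)
}

#' Create a desk-scale attention-MIL model
#'
#' The model maps per-tile feature vectors to class probabilities through
#' an optional dense tanh embedder (`dIn -> d`), attention pooling
#' (hidden width `L`) and a linear classifier head (`d -> nClasses`).
#' The head is zero-initialised (an untrained model outputs uniform
#' probabilities); embedder and attention parameters are initialised with
#' scaled Gaussian draws from `seed`.
#'
#' @param dIn input feature dimension.
#' @param nClasses number of classes (4 for IHC score, 2 for HER2 status).
#' @param d embedding width (ignored when `encoder = "identity"`).
#' @param L attention hidden width (desk default 16; the full-scale preset
#'   uses 128).
#' @param encoder `"dense"` (trainable tanh layer over the input features,
#'   the end-to-end mode) or `"identity"` (frozen features).
#' @param gated use gated attention?
#' @param seed initialisation seed.
#' @return an object of class `milModel`.
#' @export
createMilModel <- function(dIn, nClasses, d = 16L, L = 16L,
                           encoder = c("dense", "identity"),
                           gated = FALSE, seed = 1L) {
  encoder <- match.arg(encoder)
  if (encoder == "identity") d <- dIn
  params <- withSeed(deriveSeed(seed, "init"), {
    p <- list(
      V = matrix(stats::rnorm(L * d, sd = 1 / sqrt(d)), L, d),
      w = stats::rnorm(L, sd = 1 / sqrt(L)),
      Wh = matrix(0, d, nClasses),
      bh = rep(0, nClasses)
    )
    if (encoder == "dense") {
      p$We <- matrix(stats::rnorm(dIn * d, sd = 1 / sqrt(dIn)), dIn, d)
      p$be <- rep(0, d)
    }
    if (gated) p$U <- matrix(stats::rnorm(L * d, sd = 1 / sqrt(d)), L, d)
    p
  })
  structure(list(params = params,
                 config = list(dIn = dIn, d = d, L = L, nClasses = nClasses,
                               encoder = encoder, gated = gated, seed = seed)),
            class = "milModel")
}

#' @export
print.milModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "attention-MIL model: %s encoder %d -> %d, attention width %d, %d classes%s\n",
    cfg$encoder, cfg$dIn, cfg$d, cfg$L, cfg$nClasses,
    if (cfg$gated) " (gated)" else ""))
  invisible(x)
}

# forward pass on a feature matrix; returns intermediates for backprop
milForwardMatrix <- function(X, model) {
  X <- rbind(X)
  if (nrow(X) == 0L) stop("empty bag")
  p <- model$params
  assertFinite(X, "input features")
  H <- if (model$config$encoder == "dense") {
    tanh(sweep(X %*% p$We, 2, p$be, "+"))
  } else X
  assertFinite(H, "embeddings")
  a <- attentionScores(H, p, gated = model$config$gated)
  z <- drop(crossprod(H, a))
  logits <- drop(z %*% p$Wh) + p$bh
  assertFinite(logits, "classifier head")
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  list(probs = probs, attention = a, z = z, H = H, X = X, logits = logits)
}

#' Full MIL forward pass on a tile bag
#'
#' Encodes the tiles of a bag with `encoderFn` (default: the stain-aware
#' [tileFeatures()] featuriser), pools them with attention and classifies
#' the bag. Attention weights come back aligned with the bag's grid
#' coordinates, ready for heatmapping.
#'
#' @param bag a [TileBag-class] (or a pre-computed `n x dIn` feature
#'   matrix).
#' @param model a `milModel` from [createMilModel()].
#' @param encoderFn function mapping a [TileBag-class] to an `n x dIn`
#'   feature matrix; ignored when `bag` is already a matrix.
#' @param profile stain profile forwarded to the default featuriser.
#' @return list with `probs` (length `nClasses`, sums to 1), `attention`
#'   (weights), and `coords` (grid coordinates, `NULL` for matrix input).
#' @export
milForward <- function(bag, model, encoderFn = NULL,
                       profile = rjHDABProfile()) {
  if (is(bag, "TileBag")) {
    if (nTiles(bag) == 0L)
      stop(sprintf("empty bag for spot '%s'", spotId(bag)))
    enc <- encoderFn %||% function(b) tileFeatures(b, profile)
    X <- enc(bag)
    coords <- tileCoords(bag)
  } else {
    X <- rbind(bag)
    coords <- NULL
  }
  fw <- milForwardMatrix(X, model)
  list(probs = fw$probs, attention = fw$attention, coords = coords)
}

# loss and analytic gradients of one bag (cross-entropy); verified against
# finite differences in the test suite
milGradients <- function(X, y, model) {
  p <- model$params
  fw <- milForwardMatrix(X, model)
  n <- nrow(fw$H); C <- model$config$nClasses
  dlogits <- fw$probs
  dlogits[y] <- dlogits[y] - 1
  g <- list(
    Wh = outer(fw$z, dlogits),
    bh = dlogits
  )
  dz <- drop(p$Wh %*% dlogits)                       # d
  dH <- fw$attention %o% dz                          # n x d (z-path)
  da <- drop(fw$H %*% dz)                            # n
  ds <- fw$attention * (da - sum(fw$attention * da)) # softmax backprop
  Tm <- tanh(fw$H %*% t(p$V))                        # n x L
  if (model$config$gated) {
    G <- stats::plogis(fw$H %*% t(p$U))
    g$w <- drop(crossprod(Tm * G, ds))
    dA <- ds %o% p$w
    dT <- dA * G
    dG <- dA * Tm
    dpre <- dT * (1 - Tm^2)
    dpreU <- dG * G * (1 - G)
    g$V <- crossprod(dpre, fw$H)
    g$U <- crossprod(dpreU, fw$H)
    dH <- dH + dpre %*% p$V + dpreU %*% p$U
  } else {
    g$w <- drop(crossprod(Tm, ds))
    dpre <- (ds %o% p$w) * (1 - Tm^2)
    g$V <- crossprod(dpre, fw$H)
    dH <- dH + dpre %*% p$V
  }
  if (model$config$encoder == "dense") {
    dH0 <- dH * (1 - fw$H^2)
    g$We <- crossprod(fw$X, dH0)
    g$be <- colSums(dH0)
  }
  list(loss = -log(max(fw$probs[y], 1e-12)), grads = g, probs = fw$probs)
}

#' Stain-aware tile featuriser (desk-scale encoder)
#'
#' The desk-scale stand-in for a CNN tile encoder: each tile is colour
#' deconvolved with `profile` and summarised by intensity and morphology
#' statistics of its DAB and hematoxylin concentration planes — means,
#' maxima, quantiles, stained-area fractions, gradient energy, and
#' connected-component statistics of the thresholded DAB mask (component
#' count, mean component size, boundary-to-area ratio). The morphology
#' statistics let the MIL classifier see membranous-ring versus blob
#' staining patterns that share the same mean intensity.
#'
#' @param bag a [TileBag-class].
#' @param profile a [StainProfile-class].
#' @param maskThreshold DAB concentration threshold defining the stained
#'   mask (default 0.25).
#' @return `n x 13` feature matrix, one row per tile.
#' @export
tileFeatures <- function(bag, profile = rjHDABProfile(),
                         maskThreshold = 0.25) {
  stopifnot(is(bag, "TileBag"))
  n <- nTiles(bag)
  if (n == 0L) stop(sprintf("empty bag for spot '%s'", spotId(bag)))
  out <- matrix(0, n, 13L)
  colnames(out) <- c("dab_mean", "dab_max", "dab_q90", "dab_sd",
                     "dab_frac_lo", "dab_frac_hi", "hema_mean", "hema_frac",
                     "dab_grad", "mask_boundary", "mask_ncomp",
                     "mask_compsize", "tissue_frac")
  for (k in seq_len(n)) {
    conc <- deconvolveStains(rgbToOD(bag@tiles[[k]]), profile)
    D <- conc[, , 2]  # DAB plane
    Hm <- conc[, , 1]
    mask <- D > maskThreshold
    gr <- mean(abs(diff(D))) + mean(abs(t(diff(t(D)))))
    if (any(mask)) {
      lab <- labelComponents(mask)
      ncomp <- max(lab)
      inner <- mask[-1, -1] & mask[-nrow(mask), -1] &
        mask[-1, -ncol(mask)] & mask[-nrow(mask), -ncol(mask)]
      boundary <- 1 - sum(inner) / sum(mask)
      compsize <- sum(mask) / ncomp / length(mask)
    } else {
      ncomp <- 0; boundary <- 0; compsize <- 0
    }
    odSum <- rgbToOD(bag@tiles[[k]])
    tissue <- mean(odSum[, , 1] + odSum[, , 2] + odSum[, , 3] > 0.15)
    out[k, ] <- c(mean(D), max(D), stats::quantile(D, 0.9, names = FALSE),
                  stats::sd(D), mean(D > 0.1), mean(D > 0.5),
                  mean(Hm), mean(Hm > 0.3), gr, boundary,
                  min(ncomp, 50) / 10, compsize * 20, tissue)
  }
  assertFinite(out, "tile features")
  out
}

# 4-connected component labelling by vectorised label propagation:
# initialise each mask pixel with its own index and repeatedly take the
# minimum over the 4-neighbourhood until stable, then densify labels.
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    new[-1, ] <- pmin(new[-1, ], lab[-nr, ])
    new[-nr, ] <- pmin(new[-nr, ], lab[-1, ])
    new[, -1] <- pmin(new[, -1], lab[, -nc])
    new[, -nc] <- pmin(new[, -nc], lab[, -1])
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) out[mask] <- as.integer(factor(lab[mask]))
  out
}

#' Create the desk-scale whole-image classifier
#'
#' A small residual convolutional network over the downscaled spot: each
#' block applies two 3x3 convolutions with a ReLU and an identity-mapped
#' skip connection (1x1 projection when the channel count changes), followed
#' by 2x2 average pooling; global average pooling then feeds a linear head.
#' The convolutional trunk uses fixed He-style random initialisation from
#' `seed` (training fits the head on the pooled trunk features; full-scale
#' end-to-end conv training is out of desk scope), and the head is
#' zero-initialised, so an untrained model outputs uniform probabilities.
#'
#' @param inputSide expected input side in pixels (desk default 64).
#' @param nClasses number of classes.
#' @param channels channel counts of the successive residual blocks.
#' @param seed initialisation seed for the trunk.
#' @return an object of class `wholeImageModel`.
#' @export
createWholeImageModel <- function(inputSide = 64L, nClasses = 2L,
                                  channels = c(8L, 16L, 32L), seed = 1L) {
  blocks <- withSeed(deriveSeed(seed, "init"), {
    cin <- 3L
    lapply(channels, function(cout) {
      b <- list(
        w1 = array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                   c(3, 3, cin, cout)),
        w2 = array(stats::rnorm(9 * cout * cout, sd = sqrt(2 / (9 * cout))),
                   c(3, 3, cout, cout)),
        proj = if (cin != cout)
          matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
      )
      cin <<- cout
      b
    })
  })
  d <- channels[length(channels)]
  structure(list(blocks = blocks,
                 head = list(Wh = matrix(0, d, nClasses),
                             bh = rep(0, nClasses)),
                 config = list(inputSide = as.integer(inputSide),
                               nClasses = nClasses, channels = channels,
                               seed = seed)),
            class = "wholeImageModel")
}

# 3x3 same-padding convolution via im2col; x is H x W x Cin
conv3x3 <- function(x, w) {
  d <- dim(x); h <- d[1]; wd <- d[2]; cin <- d[3]
  cout <- dim(w)[4]
  xp <- array(0, c(h + 2, wd + 2, cin))
  xp[2:(h + 1), 2:(wd + 1), ] <- x
  cols <- matrix(0, h * wd, 9 * cin)
  k <- 0L
  for (cc in 1:cin) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    cols[, k] <- xp[di + seq_len(h), dj + seq_len(wd), cc]
  }
  W <- matrix(0, 9 * cin, cout)
  k <- 0L
  for (cc in 1:cin) for (dj in 1:3) for (di in 1:3) {
    k <- k + 1L
    W[k, ] <- w[di, dj, cc, ]
  }
  array(cols %*% W, c(h, wd, cout))
}

avgPool2 <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  out <- array(0, c(h2, w2, d[3]))
  i <- seq_len(h2) * 2L; j <- seq_len(w2) * 2L
  for (cc in seq_len(d[3]))
    out[, , cc] <- (x[i - 1, j - 1, cc] + x[i, j - 1, cc] +
                    x[i - 1, j, cc] + x[i, j, cc]) / 4
  out
}

# trunk features: OD-transformed input through the residual blocks, then
# global average pooling
wholeImageFeatures <- function(image, model) {
  stopifnot(is(image, "SpotImage"))
  d <- dim(pixels(image))
  if (d[1] != model$config$inputSide || d[2] != model$config$inputSide)
    stop(sprintf("expected a %d x %d input, got %d x %d (downscale first)",
                 model$config$inputSide, model$config$inputSide, d[1], d[2]))
  x <- rgbToOD(image)
  for (b in model$blocks) {
    y <- pmax(conv3x3(x, b$w1), 0)
    y <- conv3x3(y, b$w2)
    skip <- if (is.null(b$proj)) x else {
      dd <- dim(x)
      array(matrix(x, dd[1] * dd[2], dd[3]) %*% b$proj,
            c(dd[1], dd[2], ncol(b$proj)))
    }
    x <- avgPool2(pmax(y + skip, 0))
  }
  apply(x, 3, mean)
}

#' Whole-image classifier forward pass
#'
#' Class probabilities for a (pre-downscaled) spot image from the residual
#' conv trunk and linear head of [createWholeImageModel()]. Inference is
#' deterministic: the same image always yields bit-identical output.
#'
#' @param image a [SpotImage-class] with side `model$config$inputSide`.
#' @param model a `wholeImageModel`.
#' @return probability vector of length `nClasses`, summing to 1.
#' @export
wholeImageForward <- function(image, model) {
  stopifnot(inherits(model, "wholeImageModel"))
  f <- wholeImageFeatures(image, model)
  logits <- drop(f %*% model$head$Wh) + model$head$bh
  assertFinite(logits, "whole-image head")
  e <- exp(logits - max(logits))
  e / sum(e)
}
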