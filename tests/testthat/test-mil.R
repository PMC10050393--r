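test_that("attention weights normalise and match hand-computed values", {
  p <- list(V = matrix(c(1, 0), 1, 2), w = 1)
  expect_equal(attentionScores(matrix(c(3, -1), 1, 2), p), 1.0)
  H4 <- matrix(rep(c(0.4, -0.2), each = 4), 4, 2)
  expect_equal(attentionScores(H4, p), rep(0.25, 4))
  # d = 2, L = 1, V = [[1, 0]], w = [1], H = [[0,0],[10,0]]:
  # scores are tanh(0) and tanh(10); weights the softmax of those
  H <- rbind(c(0, 0), c(10, 0))
  hand <- exp(c(tanh(0), tanh(10)))
  hand <- hand / sum(hand)
  expect_equal(attentionScores(H, p), hand, tolerance = 1e-12)
  expect_error(attentionScores(matrix(0, 0, 2), p), "empty bag")
})

test_that("bag aggregation is permutation- and duplication-invariant", {
  set.seed(1)
  H <- matrix(rnorm(5 * 3), 5, 3)
  p <- list(V = matrix(rnorm(6), 2, 3), w = rnorm(2))
  a <- attentionScores(H, p)
  z <- aggregateBag(H, a)$z
  expect_equal(aggregateBag(H[1, , drop = FALSE], 1)$z, H[1, ])
  perm <- sample(5)
  expect_equal(aggregateBag(H[perm, ], attentionScores(H[perm, ], p))$z, z)
  dup <- rbind(H, H)
  expect_equal(aggregateBag(dup, attentionScores(dup, p))$z, z)
  expect_error(aggregateBag(H, a[1:3]), "mismatch")
})

test_that("MIL forward pass is uniform when untrained and bag-order free", {
  m <- createMilModel(dIn = 4, nClasses = 4, d = 6, L = 3, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(7 * 4), 7, 4)
  fw <- milForward(X, m)
  expect_equal(fw$probs, rep(0.25, 4))  # zero-initialised head
  expect_equal(sum(fw$attention), 1)
  expect_true(all(fw$attention >= 0))
  # give the head weights; invariances must still hold
  m$params$Wh <- matrix(rnorm(24, sd = 0.5), 6, 4)
  fw <- milForward(X, m)
  perm <- sample(7)
  fwP <- milForward(X[perm, ], m)
  expect_equal(fwP$probs, fw$probs)
  expect_equal(fwP$attention, fw$attention[perm])
  # duplicating every tile leaves the prediction unchanged
  fwD <- milForward(rbind(X, X), m)
  expect_equal(fwD$probs, fw$probs)
  # a bag of n copies of one tile predicts like the single-tile bag
  one <- X[3, , drop = FALSE]
  expect_equal(milForward(one[rep(1, 9), ], m)$probs,
               milForward(one, m)$probs)
})

test_that("backprop matches finite differences on tiny bags", {
  set.seed(4)
  relErr <- function(model) {
    X <- matrix(rnorm(3 * 4), 3, 4)
    model$params$Wh <- matrix(rnorm(length(model$params$Wh), sd = 0.4),
                              nrow(model$params$Wh), ncol(model$params$Wh))
    gr <- her2mil:::milGradients(X, 2L, model)
    worst <- 0
    eps <- 1e-6
    for (nm in names(gr$grads)) {
      p <- model$params[[nm]]
      for (i in seq_along(p)) {
        m1 <- model; m1$params[[nm]][i] <- p[i] + eps
        m2 <- model; m2$params[[nm]][i] <- p[i] - eps
        num <- (her2mil:::milGradients(X, 2L, m1)$loss -
                her2mil:::milGradients(X, 2L, m2)$loss) / (2 * eps)
        denom <- max(abs(num), abs(gr$grads[[nm]][i]), 1e-6)
        worst <- max(worst, abs(num - gr$grads[[nm]][i]) / denom)
      }
    }
    worst
  }
  expect_lt(relErr(createMilModel(4, 2, d = 5, L = 3, seed = 5)), 1e-4)
  expect_lt(relErr(createMilModel(4, 2, encoder = "identity", L = 3,
                                  seed = 6)), 1e-4)
  expect_lt(relErr(createMilModel(4, 2, d = 5, L = 3, gated = TRUE,
                                  seed = 7)), 1e-4)
})

test_that("whole-image classifier is deterministic and shape-checked", {
  m <- createWholeImageModel(inputSide = 32, nClasses = 2,
                             channels = c(4, 8), seed = 8)
  set.seed(9)
  img <- SpotImage(array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)), "wi")
  p1 <- wholeImageForward(img, m)
  expect_equal(p1, rep(0.5, 2))          # zero-initialised head
  m$head$Wh <- matrix(rnorm(16, sd = 0.3), 8, 2)
  p1 <- wholeImageForward(img, m)
  expect_equal(sum(p1), 1)
  expect_identical(wholeImageForward(img, m), p1)  # bit-identical re-run
  # constant image: flipping changes nothing, so outputs agree exactly
  flat <- SpotImage(array(180, c(32, 32, 3)), "flat")
  expect_identical(
    wholeImageForward(SpotImage(flipLR(pixels(flat)), "f"), m),
    wholeImageForward(flat, m))
  expect_error(wholeImageForward(
    SpotImage(array(0, c(16, 16, 3)), "small"), m), "downscale")
})

test_that("tile features capture staining pattern differences", {
  # a ring and a same-mass fragmented ring at one peak OD should separate on
  # connectivity features, not on mean intensity
  ringSpot <- generateSpot(syntheticSpotSpec(2, 1, "morphology_only",
                                             sidePx = 96, seed = 10))
  fragSpot <- generateSpot(syntheticSpotSpec(2, 0, "morphology_only",
                                             sidePx = 96, seed = 10))
  fr <- tileFeatures(tileImage(ringSpot$image, 32, discardEmpty = TRUE))
  ff <- tileFeatures(tileImage(fragSpot$image, 32, discardEmpty = TRUE))
  # fragmented staining has more connected components per tile
  expect_gt(mean(ff[, "mask_ncomp"]), mean(fr[, "mask_ncomp"]))
})

test_that("checkpoints survive a JSON round trip", {
  m <- createMilModel(dIn = 5, nClasses = 2, d = 4, L = 3, seed = 11)
  set.seed(12)
  m$params$Wh <- matrix(rnorm(8), 4, 2)
  p <- withr::local_tempfile(fileext = ".json")
  writeCheckpoint(m, p)
  back <- readCheckpoint(p)
  X <- matrix(rnorm(6 * 5), 6, 5)
  expect_equal(milForward(X, back)$probs, milForward(X, m)$probs,
               tolerance = 1e-12)
})
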