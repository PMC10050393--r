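test_that("Beer-Lambert transform matches closed-form values", {
  expect_equal(rgbToOD(array(255, c(1, 1, 3)))[1, 1, ], c(0, 0, 0))
  expect_equal(rgbToOD(array(25.5, c(1, 1, 3)))[1, 1, ], c(1, 1, 1))
  # black clips to intensity 1: OD = log10(255) per channel
  expect_equal(rgbToOD(array(0, c(1, 1, 3)))[1, 1, ],
               rep(log10(255), 3), tolerance = 1e-12)
  # od <-> rgb round trip away from the clip region
  set.seed(1)
  od <- array(runif(4 * 4 * 3, 0, 2), c(4, 4, 3))
  expect_equal(rgbToOD(odToRGB(od)), od, tolerance = 1e-10)
})

test_that("deconvolution solves the stain system", {
  prof <- rjHDABProfile()
  # pure DAB at concentration 0.7
  od <- array(rep(0.7 * stainMatrix(prof)[2, ], each = 4), c(2, 2, 3))
  conc <- deconvolveStains(od, prof)
  expect_equal(conc[1, 1, ], c(0, 0.7, 0), tolerance = 1e-10)
  # identity stain matrix: concentrations equal OD
  idProf <- StainProfile(diag(3))
  set.seed(2)
  rnd <- array(runif(12, 0, 1), c(2, 2, 3))
  expect_equal(deconvolveStains(rnd, idProf), rnd, tolerance = 1e-12)
  # random OD against an independent 3x3 linear solve
  for (i in 1:10) {
    p <- randomStainProfile()
    odv <- runif(3, 0, 2)
    got <- deconvolveStains(array(odv, c(1, 1, 3)), p)[1, 1, ]
    oracle <- solve(t(stainMatrix(p)), odv)
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  bad <- rjHDABProfile()
  bad@stainMatrix[2, ] <- bad@stainMatrix[1, ]
  expect_error(deconvolveStains(rnd, bad), "singular")
})

test_that("convolve(deconvolve(od)) round trips to 1e-8", {
  set.seed(3)
  for (i in 1:10) {
    p <- randomStainProfile()
    od <- array(runif(8 * 8 * 3, 0, 2.2), c(8, 8, 3))
    expect_equal(convolveStains(deconvolveStains(od, p), p), od,
                 tolerance = 1e-8)
  }
})

test_that("Macenko estimation recovers planted stain vectors", {
  set.seed(4)
  angles <- replicate(5, {
    p <- randomStainProfile()
    est <- macenkoEstimate(randomStainImage(p))
    c(angleDeg(stainMatrix(est)[1, ], stainMatrix(p)[1, ]),
      angleDeg(stainMatrix(est)[2, ], stainMatrix(p)[2, ]))
  })
  expect_lt(max(angles), 2)
})

test_that("Macenko rejects degenerate inputs", {
  expect_error(macenkoEstimate(SpotImage(array(255, c(32, 32, 3)), "w")),
               "degenerate")
  # single pure stain: rank-1 OD cloud (one weight per pixel, common vector)
  prof <- rjHDABProfile()
  w <- runif(1024, 0.3, 1)
  od <- array(rep(stainMatrix(prof)[2, ], each = 1024) * rep(w, 3),
              c(32, 32, 3))
  expect_error(macenkoEstimate(SpotImage(odToRGB(od), "mono")), "rank-1")
})

test_that("Macenko is invariant to pixel shuffling and duplication", {
  set.seed(5)
  p <- randomStainProfile()
  img <- randomStainImage(p, side = 40)
  est <- macenkoEstimate(img)
  # shuffle pixels
  px <- pixels(img)
  flat <- matrix(px, 1600, 3)[sample(1600), ]
  shuf <- SpotImage(array(flat, c(40, 40, 3)), "shuf")
  expect_equal(stainMatrix(macenkoEstimate(shuf)), stainMatrix(est),
               tolerance = 1e-8)
  # duplicate every pixel (stack the image)
  dup <- SpotImage(array(rbind(matrix(px, 1600, 3), matrix(px, 1600, 3)),
                         c(80, 40, 3)), "dup")
  estDup <- macenkoEstimate(dup)
  expect_lt(angleDeg(stainMatrix(estDup)[1, ], stainMatrix(est)[1, ]), 0.1)
  expect_lt(angleDeg(stainMatrix(estDup)[2, ], stainMatrix(est)[2, ]), 0.1)
})

test_that("stain normalization is identity for equal profiles and reversible", {
  set.seed(6)
  pA <- randomStainProfile()
  img <- randomStainImage(pA, side = 32)
  estA <- macenkoEstimate(img)
  # identity: source == target
  same <- normalizeStains(img, estA, estA)
  expect_lte(max(abs(pixels(same) - pixels(img))), 2)
  # white is a fixed point
  px <- pixels(img); px[1:4, 1:4, ] <- 255
  imgW <- SpotImage(px, "w")
  normW <- normalizeStains(imgW, estA, estA)
  expect_lte(max(abs(pixels(normW)[1:4, 1:4, ] - 255)), 1)
  # A -> B -> A round trip
  pB <- rjHDABProfile(maxConcentrations = maxConcentrations(estA))
  there <- normalizeStains(img, estA, pB)
  back <- normalizeStains(there, pB, estA)
  expect_lte(max(abs(pixels(back) - pixels(img))), 3)
  # idempotence once in the target profile
  again <- normalizeStains(there, pB, pB)
  expect_lte(max(abs(pixels(again) - pixels(there))), 2)
})

test_that("mean tile DAB equals the brute-force concentration mean", {
  prof <- rjHDABProfile()
  expect_equal(meanTileDAB(array(255, c(8, 8, 3)), prof), 0)
  # constant DAB 0.8 field
  od <- array(rep(0.8 * stainMatrix(prof)[2, ], each = 64), c(8, 8, 3))
  expect_equal(meanTileDAB(odToRGB(od), prof), 0.8, tolerance = 0.01)
  # random tile vs per-pixel solve
  set.seed(7)
  tile <- array(runif(8 * 8 * 3, 30, 250), c(8, 8, 3))
  od <- rgbToOD(tile)
  oracle <- mean(apply(matrix(od, 64, 3), 1,
                       function(v) solve(t(stainMatrix(prof)), v)[2]))
  expect_equal(meanTileDAB(tile, prof), oracle, tolerance = 1e-10)
})

test_that("stain profiles survive a JSON round trip", {
  p <- withr::local_tempfile(fileext = ".json")
  prof <- rjHDABProfile(maxConcentrations = c(1.3, 0.8))
  writeStainProfile(prof, p)
  back <- readStainProfile(p)
  expect_equal(stainMatrix(back), stainMatrix(prof), tolerance = 1e-12)
  expect_equal(maxConcentrations(back), c(1.3, 0.8))
})
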