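# shared fixtures, all generated in code; cohorts and their derived objects
# are memoised so the acceptance tests and the property tests reuse them

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

getCohort <- function(regime, n = 200, seed = 1) {
  memo(paste("cohort", regime, n, seed, sep = "_"),
       generateCohort(n, regime = regime, seed = seed))
}

getFeatures <- function(regime, n = 200, seed = 1) {
  memo(paste("features", regime, n, seed, sep = "_"),
       featurizeCohort(cohortImages(getCohort(regime, n, seed))))
}

getDescriptors <- function(regime, n = 200, seed = 1) {
  memo(paste("descriptors", regime, n, seed, sep = "_"),
       cohortDescriptors(cohortImages(getCohort(regime, n, seed))))
}

# a well-conditioned random stain profile (positive unit OD rows), with the
# package's canonical row order: the smaller-blue-OD stain first
randomStainProfile <- function() {
  repeat {
    a <- abs(stats::rnorm(3)) + 0.1
    b <- abs(stats::rnorm(3)) + 0.1
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    if (abs(sum(a * b)) < 0.9 && abs(a[3] - b[3]) > 0.05) break
  }
  if (a[3] > b[3]) { tmp <- a; a <- b; b <- tmp }
  r <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  StainProfile(rbind(a, b, r / sqrt(sum(r^2))))
}

# an RGB image that mixes the first two stains of a profile with random
# positive weights (plus near-pure pixels so Macenko sees the extremes)
randomStainImage <- function(profile, side = 48) {
  n <- side * side
  wH <- stats::runif(n, 0, 1)
  wD <- stats::runif(n, 0, 0.8)
  pure <- sample(n, round(0.1 * n))
  wD[pure[seq_len(length(pure) / 2)]] <- 0
  wH[pure[-seq_len(length(pure) / 2)]] <- 0
  od <- cbind(wH, wD) %*% stainMatrix(profile)[1:2, ]
  SpotImage(odToRGB(array(od, c(side, side, 3))), "mix")
}

angleDeg <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi

# separable toy feature cohort for optimiser sanity checks: class-1 bags
# carry a few high-signal tiles, class-0 bags do not
toyFeatureCohort <- function(n = 60, nTile = 8, d = 5, seed = 42) {
  withr::with_seed(seed, {
    ids <- sprintf("toy_%02d", seq_len(n))
    status <- rep(c(0L, 1L), each = n / 2)
    feats <- lapply(seq_len(n), function(i) {
      X <- matrix(stats::rnorm(nTile * d, sd = 0.3), nTile, d)
      if (status[i] == 1L) X[sample(nTile, 2), 1] <- 4
      X
    })
    names(feats) <- ids
    labels <- data.frame(spot_id = ids,
                         ihc_score = ifelse(status == 1L, 3L, 0L),
                         her2_status = status)
    list(features = feats, labels = labels)
  })
}
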