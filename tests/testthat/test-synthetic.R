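test_that("spot generation is bit-deterministic from the spec", {
  spec <- syntheticSpotSpec(2, 1, "intensity_coded", sidePx = 96, seed = 21)
  a <- generateSpot(spec)
  b <- generateSpot(spec)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$label, b$label)
})

test_that("spec validation enforces label consistency and geometry", {
  expect_error(syntheticSpotSpec(2), "explicit status")
  expect_error(syntheticSpotSpec(0, status = 1), "negative status")
  expect_error(syntheticSpotSpec(3, status = 0), "positive status")
  expect_error(syntheticSpotSpec(1, sidePx = 100, tileSize = 32),
               "multiple of tileSize")
  expect_error(syntheticSpotSpec(5), "score")
})

test_that("rendered DAB intensity is recovered through the stain pipeline", {
  # a score-0 spot carries essentially no DAB
  s0 <- generateSpot(syntheticSpotSpec(0, regime = "intensity_coded",
                                       seed = 22))
  expect_lt(cohortDescriptors(list(s0$image))$d_max, 0.05)
  # a score-3 spot with peak OD 1.2 yields d_max within 20% of 1.2
  s3 <- generateSpot(syntheticSpotSpec(3, regime = "intensity_coded",
                                       dabPeakOD = 1.2, seed = 23))
  d3 <- cohortDescriptors(list(s3$image))$d_max
  expect_gt(d3, 1.2 * 0.8)
  expect_lt(d3, 1.2 * 1.2)
})

test_that("simulated ISH counts always reproduce the requested status", {
  set.seed(24)
  for (st in 0:1) {
    draws <- t(replicate(1000, generateIshCounts(st)))
    calls <- ishCall(draws[, 1], draws[, 2])
    expect_true(all(calls == st))
    if (st == 0) expect_true(all(draws[, 1] < 6))
  }
})

test_that("cohort apportionment hits stated class counts exactly", {
  cohEq <- generateCohort(100, classProportions = rep(0.25, 4),
                          regime = "intensity_coded", seed = 25,
                          sidePx = 32, tileSize = 32)
  expect_equal(as.integer(table(factor(cohortLabels(cohEq)$ihc_score,
                                       levels = 0:3))),
               rep(25L, 4))
  # the external-cohort distribution at its published size
  cohExt <- generateCohort(653, regime = "intensity_coded", seed = 26,
                           sidePx = 32, tileSize = 32)
  expect_equal(as.integer(table(factor(cohortLabels(cohExt)$ihc_score,
                                       levels = 0:3))),
               c(416L, 186L, 14L, 37L))
  expect_error(generateCohort(2, regime = "intensity_coded"),
               "too small")
})

test_that("cohort label files are identical across runs with one seed", {
  a <- generateCohort(12, regime = "morphology_only", seed = 27,
                      sidePx = 64, tileSize = 32)
  b <- generateCohort(12, regime = "morphology_only", seed = 27,
                      sidePx = 64, tileSize = 32)
  expect_identical(cohortLabels(a), cohortLabels(b))
  expect_identical(pixels(cohortImages(a)[[5]]), pixels(cohortImages(b)[[5]]))
})

test_that("every generated label passes the clinical consistency rules", {
  lab <- cohortLabels(getCohort("intensity_coded"))
  nonEq <- lab[lab$ihc_score != 2, ]
  expect_equal(scoreToStatus(nonEq$ihc_score), nonEq$her2_status)
  eq <- lab[lab$ihc_score == 2, ]
  if (nrow(eq)) {
    expect_false(anyNA(eq$her2_signals))
    expect_equal(ishCall(eq$her2_signals, eq$cen17_signals), eq$her2_status)
  }
  labM <- cohortLabels(getCohort("morphology_only"))
  expect_true(all(labM$ihc_score == 2))
  expect_equal(ishCall(labM$her2_signals, labM$cen17_signals),
               labM$her2_status)
})

test_that("mean staining intensity rises monotonically with score", {
  # tested on a score-balanced cohort: with the imbalanced default
  # proportions the tie structure alone caps Spearman's rho at ~0.85 even
  # for a perfectly monotone descriptor, so a balanced cohort is the valid
  # probe of monotonicity
  coh <- generateCohort(200, classProportions = rep(0.25, 4),
                        regime = "intensity_coded", seed = 2)
  desc <- cohortDescriptors(cohortImages(coh))
  lab <- cohortLabels(coh)
  score <- lab$ihc_score[match(desc$spot_id, lab$spot_id)]
  rho <- cor(score, desc$d_max, method = "spearman")
  expect_gt(rho, 0.9)
  # group means are strictly increasing, and groups do not even overlap
  mns <- tapply(desc$d_max, score, mean)
  expect_true(all(diff(mns) > 0))
  # on the imbalanced default cohort the descriptor still separates groups
  descI <- getDescriptors("intensity_coded")
  labI <- cohortLabels(getCohort("intensity_coded"))
  scoreI <- labI$ihc_score[match(descI$spot_id, labI$spot_id)]
  expect_true(all(diff(tapply(descI$d_max, scoreI, mean)) > 0))
})

test_that("morphology-only spots carry no intensity signal for status", {
  desc <- getDescriptors("morphology_only")
  lab <- cohortLabels(getCohort("morphology_only"))
  st <- lab$her2_status[match(desc$spot_id, lab$spot_id)]
  p <- stats::wilcox.test(desc$d_max[st == 1], desc$d_max[st == 0])$p.value
  expect_gt(p, 0.05)
})

test_that("cohorts write a complete on-disk bundle", {
  coh <- generateCohort(4, regime = "intensity_coded", seed = 28,
                        sidePx = 64, tileSize = 32)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 4)
  lab <- readLabels(file.path(dir, "labels.csv"))
  expect_equal(lab$spot_id, cohortLabels(coh)$spot_id)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$regime, "intensity_coded")
})
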