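test_that("sectional thresholds are strict and monotone", {
  sc <- tinyScene(71, size = 48)
  tile <- sceneImage(sc)
  lo <- sectionGrid(c(0, 48), c(0, 48), matrix(min(pixels(tile)) - 1, 1, 1))
  hi <- sectionGrid(c(0, 48), c(0, 48), matrix(max(pixels(tile)), 1, 1))
  expect_true(all(sectionalThreshold(tile, lo) == 1L))
  expect_true(all(sectionalThreshold(tile, hi) == 0L))
  # raising a section's threshold never adds foreground
  g1 <- sectionGrid(c(0, 24, 48), c(0, 48), matrix(c(10000, 20000), 2, 1))
  g2 <- sectionGrid(c(0, 24, 48), c(0, 48), matrix(c(18000, 20000), 2, 1))
  m1 <- sectionalThreshold(tile, g1)
  m2 <- sectionalThreshold(tile, g2)
  expect_true(all(m2 <= m1))
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_error(sectionalThreshold(tile, sectionGrid(c(0, 32), c(0, 48),
                                                    matrix(1, 1, 1))),
               "do not match")
})

test_that("per-section thresholds beat a global threshold under a
           background step", {
  # two halves with identical cell-background contrast but a +12000 grey
  # background step: per-section thresholds recover cells in both halves,
  # a single global threshold cannot
  set.seed(72)
  img <- matrix(10000, 64, 64)
  img[, 33:64] <- 22000
  truth <- matrix(0L, 64, 64)
  for (ctr in list(c(16, 16), c(48, 16), c(16, 48), c(48, 48))) {
    for (r in -3:3) for (c in -3:3) if (r^2 + c^2 <= 9) {
      img[ctr[1] + r, ctr[2] + c] <- img[ctr[1] + r, ctr[2] + c] + 8000
      truth[ctr[1] + r, ctr[2] + c] <- 1L
    }
  }
  tile <- imageTile(img, 16L, 1)
  grid <- autoSectionThresholds(tile, c(1, 2))
  mSec <- sectionalThreshold(tile, grid)
  expect_identical(mSec, truth)
  best <- 0
  for (t in seq(9000, 31000, by = 500)) {
    mGlob <- matrix(as.integer(img > t), 64, 64)
    best <- max(best, metricsFromCounts(confusionCounts(mGlob, truth))$dice)
  }
  expect_lt(best, 1)
})

test_that("automatic thresholds handle degenerate sections and 1x1 grids", {
  const <- imageTile(matrix(5000, 32, 32), 16L, 1)
  g <- autoSectionThresholds(const, c(2, 2))
  expect_true(all(sectionalThreshold(const, g) == 0L))
  sc <- tinyScene(73, size = 48)
  tile <- sceneImage(sc)
  g1 <- autoSectionThresholds(tile, c(1, 1))
  glob <- EBImage::otsu(EBImage::Image(pixels(tile) / 65535),
                        levels = 2^16) * 65535
  expect_equal(as.vector(g1$thresholds), glob)
})

test_that("sectional thresholding bootstraps usable initial masks", {
  # initial-mask quality on clean synthetic scenes: Dice above 0.6 against
  # generator truth (bootstrap quality, not final quality)
  dices <- vapply(1:3, function(i) {
    sc <- generateScene(sceneParams(widthPx = 96, heightPx = 96,
                                    umPerPx = 1, targetDensity = 1500,
                                    seed = 730 + i, vesselCount = 1L))
    m <- sectionalThreshold(sceneImage(sc),
                            autoSectionThresholds(sceneImage(sc), c(3, 3)))
    metricsFromCounts(confusionCounts(m, sceneMask(sc)))$dice
  }, numeric(1))
  expect_gt(mean(dices), 0.6)
})

test_that("bootstrap prediction binarizes probability maps at the
           exposed threshold", {
  trainSet <- lapply(1:4, function(i) tinySample(240 + i, i, size = 32L))
  fit <- trainModel(buildUnetBaseline(modelConfig(depth = 1,
                                                  baseChannels = 4,
                                                  useResidual = FALSE),
                                      seed = 5),
                    trainSet[1:3], trainSet[4],
                    trainConfig(epochs = 1, lr = 3e-3, batchSize = 2,
                                seed = 10), loss = "bce")
  tile <- trainSet[[1]]$image
  rough <- bootstrapPredict(fit$model, tile)
  prob <- predictProb(fit$model, tile)
  expect_identical(rough, matrix(as.integer(prob > 0.5), 32, 32))
  expect_true(all(rough %in% c(0L, 1L)))
  untrained <- buildUnetBaseline(modelConfig(depth = 1, baseChannels = 4,
                                             useResidual = FALSE), seed = 6)
  expect_error(bootstrapPredict(untrained, tile), "not been trained")
})

test_that("masks round-trip through editable 0/255 PNGs", {
  m <- matrix(rbinom(64, 1, 0.4), 8)
  f <- withr::local_tempfile(fileext = ".png")
  writeMaskPng(m, f)
  expect_identical(readMaskPng(f), matrix(as.integer(m), 8, 8))
})
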