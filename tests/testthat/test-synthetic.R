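test_that("scene generation is bit-identical for equal seeds", {
  p <- sceneParams(widthPx = 96, heightPx = 96, seed = 11)
  s1 <- generateScene(p)
  s2 <- generateScene(p)
  expect_identical(pixels(sceneImage(s1)), pixels(sceneImage(s2)))
  expect_identical(sceneMask(s1), sceneMask(s2))
  expect_identical(sceneRegions(s1), sceneRegions(s2))
  s3 <- generateScene(sceneParams(widthPx = 96, heightPx = 96, seed = 12))
  expect_false(identical(pixels(sceneImage(s1)), pixels(sceneImage(s3))))
})

test_that("zero target density gives an all-background scene", {
  s <- generateScene(sceneParams(widthPx = 64, heightPx = 64,
                                 targetDensity = 0, seed = 1))
  expect_identical(sum(sceneMask(s)), 0L)
  expect_identical(trueDensity(s), 0)
  expect_identical(nrow(sceneRegions(s)), 0L)
})

test_that("degenerate geometry is rejected with a diagnostic", {
  expect_error(generateScene(sceneParams(widthPx = 32, heightPx = 32,
                                         umPerPx = 20, seed = 1)),
               "degenerate geometry")
})

test_that("parameter validity is enforced", {
  expect_error(sceneParams(umPerPx = -1), "umPerPx")
  expect_error(sceneParams(clusterProb = 1.5), "clusterProb")
  expect_error(sceneParams(cellEccRange = c(0.5, 1.2)), "cellEccRange")
})

test_that("realized counts are Poisson around target density", {
  # Monte-Carlo oracle: mean count over independent scenes within 3
  # standard errors of density x area, and relative error of the realized
  # density under 2%
  lam <- 1500 * tileAreaMm2(220, 220, 1)
  counts <- vapply(1:150, function(i) nrow(sceneRegions(generateScene(
    sceneParams(widthPx = 220, heightPx = 220, umPerPx = 1,
                targetDensity = 1500, seed = 4000 + i, vesselCount = 0,
                artifactRate = 0, clusterProb = 0.3)))), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
  expect_lt(abs(mean(counts) / lam - 1), 0.02)
})

test_that("every foreground pixel belongs to exactly one truth region", {
  s <- generateScene(sceneParams(widthPx = 128, heightPx = 128, umPerPx = 1,
                                 seed = 5, clusterProb = 0.5))
  expect_identical(sum(sceneMask(s)), sum(sceneRegions(s)$area_px))
  expect_equal(trueDensity(s),
               nrow(sceneRegions(s)) / tileAreaMm2(128, 128, 1))
})

test_that("artifacts never enter the mask and vessels only darken", {
  base <- sceneParams(widthPx = 80, heightPx = 80, umPerPx = 1, seed = 3,
                      artifactRate = 0, vesselCount = 0, noiseSd = 0)
  withArt <- base; withArt@artifactRate <- 80
  withVes <- base; withVes@vesselCount <- 3L
  s0 <- generateScene(base)
  sA <- generateScene(withArt)
  sV <- generateScene(withVes)
  expect_identical(sceneMask(s0), sceneMask(sA))
  expect_true(all(pixels(sceneImage(sA)) >= pixels(sceneImage(s0))))
  expect_true(all(pixels(sceneImage(sV)) <= pixels(sceneImage(s0))))
  expect_true(any(pixels(sceneImage(sV)) < pixels(sceneImage(s0))))
})

test_that("clustered cells touch while staying distinct truth regions", {
  s <- generateScene(sceneParams(widthPx = 128, heightPx = 128, umPerPx = 1,
                                 targetDensity = 2000, seed = 9,
                                 clusterProb = 0.6))
  reg <- sceneRegions(s)
  expect_gt(nrow(reg), 0)
  expect_true(any(duplicated(reg$cluster)))
  # merged under 8-connectivity: fewer components than truth regions
  comp <- extractRegions(sceneMask(s), 1, minAreaPx = 0)
  expect_lt(nrow(comp), nrow(reg))
})

test_that("mosaics carry per-tile densities and physical spacing", {
  p <- sceneParams(widthPx = 48, heightPx = 48, umPerPx = 1, seed = 2)
  mo <- generateMosaic(2, 3, matrix(c(0, 1000, 2000, 0, 1000, 2000), 2, 3),
                       p)
  expect_length(mosaicScenes(mo), 6)
  expect_equal(spacingMm(mo), c(0.048, 0.048))
  lay <- mosaicLayout(mo)
  expect_equal(lay$x_mm[lay$col == 2][1], 0.048)
  # stated region size fixes the pitch: 8 x 8 over 20 x 20 mm -> 2.5 mm
  mo2 <- generateMosaic(8, 8, 0, p, regionMm = c(20, 20))
  expect_equal(spacingMm(mo2), c(2.5, 2.5))
  # single tile
  mo1 <- generateMosaic(1, 1, 1500, p)
  expect_length(mosaicScenes(mo1), 1)
  expect_error(generateMosaic(2, 2, matrix(c(1, NA, 1, 1), 2), p),
               "missing")
})

test_that("scene round-trips to disk as TIFF/PNG/CSV", {
  s <- generateScene(sceneParams(widthPx = 48, heightPx = 48, umPerPx = 1,
                                 seed = 6))
  d <- withr::local_tempdir()
  paths <- writeScene(s, d, "t1")
  expect_true(all(file.exists(paths)))
  t2 <- readTile(paths["image"], umPerPx = 1)
  expect_equal(pixels(t2), pixels(sceneImage(s)), ignore_attr = TRUE)
  m2 <- readMaskPng(paths["mask"])
  expect_identical(m2, sceneMask(s))
  r2 <- read.csv(paths["regions"])
  expect_equal(nrow(r2), nrow(sceneRegions(s)))
})
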