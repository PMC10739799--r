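test_that("binarization is the strict pixelwise comparison", {
  set.seed(61)
  p <- matrix(runif(100), 10)
  m <- binarizeProb(p, 0.5)
  expect_identical(m, matrix(as.integer(p > 0.5), 10, 10))
  expect_identical(sum(binarizeProb(p, 1)), 0L)
  expect_identical(binarizeProb(p, 0), matrix(as.integer(p > 0), 10, 10))
})

test_that("region extraction recovers disk and ellipse morphometry", {
  mk <- function(f) {
    m <- matrix(0L, 40, 40)
    for (r in 1:40) for (c in 1:40) if (f(r - 20, c - 20)) m[r, c] <- 1L
    m
  }
  disk <- extractRegions(mk(function(dr, dc) dr^2 + dc^2 <= 100), 1, 0)
  expect_identical(nrow(disk), 1L)
  expect_equal(disk$area_px, 317)         # rasterized pi * 10^2
  expect_lt(disk$eccentricity, 0.05)
  expect_equal(disk$centroid_row, 19, tolerance = 0.01)  # 0-based
  ell <- extractRegions(mk(function(dr, dc) (dr / 5)^2 + (dc / 10)^2 <= 1),
                        1, 0)
  expect_equal(ell$eccentricity, sqrt(1 - 25 / 100), tolerance = 0.02)
  # single pixel: eccentricity 0 by convention; removed by the area filter
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_identical(extractRegions(single, 1, 0)$eccentricity, 0)
  expect_identical(nrow(extractRegions(single, 1, 5)), 0L)
})

test_that("touching cells merge under 8-connectivity", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[5:7, 5:7] <- 1L          # diagonal contact at (4,4)-(5,5)
  expect_identical(nrow(extractRegions(m, 1, 0)), 1L)
  m2 <- matrix(0L, 10, 10)
  m2[2:4, 2:4] <- 1L
  m2[6:8, 6:8] <- 1L         # gap of one pixel: two regions
  expect_identical(nrow(extractRegions(m2, 1, 0)), 2L)
})

test_that("density is count over physical area", {
  reg <- data.frame(id = 1:100)
  expect_equal(gcDensity(reg, 0.1), 1000)
  expect_equal(gcDensity(reg[0, , drop = FALSE], 0.5), 0)
  expect_error(gcDensity(reg, 0), "positive")
})

test_that("calibration scaling is exact: area x4, density /4", {
  sc <- tinyScene(62, size = 96, cluster = 0)
  m <- sceneMask(sc)
  r1 <- extractRegions(m, 1, 0)
  r2 <- extractRegions(m, 2, 0)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  a1 <- tileAreaMm2(96, 96, 1)
  a2 <- tileAreaMm2(96, 96, 2)
  expect_equal(gcDensity(r2, a2), gcDensity(r1, a1) / 4)
})

test_that("eccentricity is bounded and invariant under 90-degree rotation", {
  sc <- tinyScene(63, size = 96)
  m <- sceneMask(sc)
  r <- extractRegions(m, 1, 0)
  expect_true(all(r$eccentricity >= 0 & r$eccentricity < 1))
  rRot <- extractRegions(gobletseg:::rot90mat(m, 90), 1, 0)
  expect_equal(sort(r$eccentricity), sort(rRot$eccentricity),
               tolerance = 1e-9)
})

test_that("density recovery: exact without clusters, undercount with", {
  exact <- tinyScene(64, size = 128, cluster = 0)
  est <- gcDensity(extractRegions(sceneMask(exact), 1),
                   tileAreaMm2(128, 128, 1))
  expect_equal(est, trueDensity(exact))
  clustered <- tinyScene(65, size = 128, density = 2200, cluster = 0.5)
  estC <- gcDensity(extractRegions(sceneMask(clustered), 1),
                    tileAreaMm2(128, 128, 1))
  expect_lt(estC, trueDensity(clustered))
})

test_that("mosaic density maps place tiles and conserve counts", {
  p <- sceneParams(widthPx = 64, heightPx = 64, umPerPx = 1, seed = 8,
                   clusterProb = 0)
  mo <- generateMosaic(2, 2, matrix(c(800, 1200, 1600, 2000), 2, 2), p)
  dm <- densityMap(mo, minAreaPx = 0)
  expect_identical(dim(densities(dm)), c(2L, 2L))
  area <- tileAreaMm2(64, 64, 1)
  total <- sum(dm@counts)
  expect_equal(total, sum(vapply(mosaicScenes(mo),
                                 function(s) nrow(sceneRegions(s)),
                                 numeric(1))))
  # single-tile mosaic equals that tile's density
  mo1 <- generateMosaic(1, 1, 1500, p)
  dm1 <- densityMap(mo1, minAreaPx = 0)
  expect_equal(as.vector(densities(dm1)), trueDensity(mosaicScenes(mo1)[[1]]))
  # overlay renders a PNG
  f <- withr::local_tempfile(fileext = ".png")
  renderDensityOverlay(dm, mo, f)
  expect_gt(file.size(f), 0)
})

test_that("density agreement reports r, mean ratio and percentile limits", {
  man <- c(1000, 1500, 2000, 2500, 1200)
  same <- densityAgreement(man, man)
  expect_equal(same$r, 1)
  expect_equal(same$ratioMean, 1)
  expect_equal(same$limits, c(0, 0))
  scaled <- densityAgreement(0.943 * man, man)
  expect_equal(scaled$ratioMean, 0.943, tolerance = 1e-12)
  set.seed(66)
  a <- runif(50, 900, 2500)
  b <- a * runif(50, 0.8, 1.1)
  ag <- densityAgreement(a, b)
  expect_equal(ag$r, sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_error(densityAgreement(c(1, 1, 1), c(2, 2, 2)), "zero-variance")
})

test_that("timepoint comparison summarises density and size per group", {
  tiles <- data.frame(timepoint = rep(c("pre", "wk2"), each = 3),
                      tile = 1:6,
                      density = c(1500, 1600, 1550, 950, 1000, 1050))
  regions <- data.frame(timepoint = rep(c("pre", "wk2"), c(40, 25)),
                        area_um2 = c(rnorm(40, 78, 10), rnorm(25, 20, 5)))
  out <- compareTimepoints(tiles, regions)
  expect_identical(nrow(out), 2L)
  pre <- out[out$timepoint == "pre", ]
  expect_equal(pre$density_mean, 1550)
  expect_equal(pre$n_cells, 40L)
  # identical groups give identical summaries
  t2 <- tiles; t2$timepoint <- "pre"
  r2 <- regions; r2$timepoint <- "pre"
  o2 <- compareTimepoints(t2, r2)
  expect_identical(nrow(o2), 1L)
  # single-tile group has undefined sd, reported as NA
  single <- compareTimepoints(data.frame(timepoint = "x", tile = 1,
                                         density = 1200),
                              data.frame(timepoint = "x", area_um2 = 50))
  expect_true(is.na(single$density_sd))
  expect_warning(compareTimepoints(tiles[0, ],
                                   data.frame(timepoint = "y",
                                              area_um2 = 10)), "no tiles")
})
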