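# Synthetic MBFM-like scene generator with exact ground truth.
# All randomness flows through a private RNG stream seeded from the params,
# so equal seeds give bit-identical scenes and the caller's RNG state is
# left untouched.

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Physical area of a tile in mm^2
#' @param widthPx,heightPx tile size in pixels.
#' @param umPerPx micrometres per pixel.
#' @return area in mm^2.
#' @export
tileAreaMm2 <- function(widthPx, heightPx, umPerPx) {
  widthPx * heightPx * (umPerPx / 1000)^2
}

# Stamp one dark curvilinear vessel shadow (random-walk centreline with a
# Gaussian cross-section) multiplicatively onto `shadow` (values in [0,1],
# 1 = fully shadowed). Only darkens, never brightens.
renderVessel <- function(shadow, depth) {
  H <- nrow(shadow); W <- ncol(shadow)
  sigma <- runif(1, 6, 16)                 # half-width in px
  steps <- ceiling(1.5 * sqrt(H^2 + W^2))
  pos <- c(runif(1, 1, H), runif(1, 1, W))
  ang <- runif(1, 0, 2 * pi)
  turn <- rnorm(steps, 0, 0.08)
  d <- runif(1, 0.6, 1) * depth
  r <- ceiling(2.5 * sigma)
  off <- seq(-r, r)
  prof <- d * exp(-(off / sigma)^2)        # 1-D Gaussian cross-section
  for (s in seq_len(steps)) {
    ang <- ang + turn[s]
    pos <- pos + c(sin(ang), cos(ang)) * 2
    ph <- round(pos[1]); pw <- round(pos[2])
    if (ph < -r || ph > H + r || pw < -r || pw > W + r) break
    hs <- ph + off; ws <- pw + off
    hok <- hs >= 1 & hs <= H; wok <- ws >= 1 & ws <= W
    if (!any(hok) || !any(wok)) next
    patch <- outer(prof[hok], prof[wok], function(a, b) pmax(a, b) *
                     (pmin(a, b) / d)^0.25)
    sub <- shadow[hs[hok], ws[wok], drop = FALSE]
    shadow[hs[hok], ws[wok]] <- pmax(sub, patch)
  }
  shadow
}

#' Generate a synthetic goblet-cell scene
#'
#' Renders bright anti-aliased elliptical cells (Gaussian-like radial
#' intensity profile) over a smooth background gradient darkened by
#' curvilinear vessel shadows, adds small bright non-cell artifacts
#' (excluded from the mask) and Gaussian noise. The realized cell count is
#' Poisson-distributed around `targetDensity x area`. With probability
#' `clusterProb` a cell is placed touching an earlier cell, so the two merge
#' under 8-connectivity while remaining distinct regions in generator truth;
#' non-clustered cells are kept separated so that, with `clusterProb = 0`,
#' connected components recover the placed cells exactly.
#'
#' @param params a [SceneParams-class] object.
#' @return A [Scene-class]: 16-bit tile, binary mask (the union of the
#'   per-cell pixel sets, each foreground pixel owned by exactly one cell),
#'   generator-truth region table and the realized density.
#' @examples
#' sc <- generateScene(sceneParams(widthPx = 96, heightPx = 96, seed = 7))
#' trueDensity(sc)
#' @export
generateScene <- function(params) {
  validObject(params)
  meanAreaPx <- params@cellAreaMean / params@umPerPx^2
  if (meanAreaPx < 1)
    stop("degenerate geometry: mean cell area is below 1 px^2 at ",
         params@umPerPx, " um/px; refine the calibration")
  withLocalSeed(params@seed, {
    H <- params@heightPx; W <- params@widthPx
    areaMm2 <- tileAreaMm2(W, H, params@umPerPx)

    # Each rendering phase draws from its own derived seed, so changing one
    # phase's parameters (e.g. the artifact rate) cannot perturb another
    # phase's draws: the cell layout is a function of the seed alone.
    sbase <- (params@seed %% 100000000L) * 7L
    set.seed(sbase + 1L)
    # --- background: base level + tilted plane + low-frequency undulation
    rowv <- seq_len(H) / H; colv <- seq_len(W) / W
    th <- runif(1, 0, 2 * pi)
    plane <- outer(rowv, colv, function(r, c) cos(th) * r + sin(th) * c)
    ph1 <- runif(2, 0, 2 * pi); fr <- runif(2, 1, 2.5)
    wave <- outer(sin(2 * pi * fr[1] * rowv + ph1[1]),
                  sin(2 * pi * fr[2] * colv + ph1[2]))
    img <- 0.22 + params@backgroundGradientAmp * (0.7 * plane + 0.3 * wave)

    # --- vessels: multiplicative shadows (darken only)
    set.seed(sbase + 2L)
    if (params@vesselCount > 0L && params@vesselShadowDepth > 0) {
      shadow <- matrix(0, H, W)
      for (i in seq_len(params@vesselCount))
        shadow <- renderVessel(shadow, params@vesselShadowDepth)
      img <- img * (1 - shadow)
    }

    # --- cells: Poisson count, sequential placement
    set.seed(sbase + 3L)
    nCells <- rpois(1, params@targetDensity * areaMm2)
    label <- matrix(0L, H, W)
    bestR2 <- matrix(Inf, H, W)
    placed <- 0L
    cy <- cx <- aa <- bb <- numeric(0)
    clusterId <- integer(0)
    for (i in seq_len(nCells)) {
      S <- max(params@cellAreaMean / 4,
               rnorm(1, params@cellAreaMean, params@cellAreaSd))
      e <- runif(1, params@cellEccRange[1], params@cellEccRange[2])
      rho <- sqrt(1 - e^2)
      aPx <- sqrt(S / (pi * rho)) / params@umPerPx  # semi-major, px
      bPx <- aPx * rho                              # semi-minor, px
      theta <- runif(1, 0, pi)
      amp <- runif(1, 0.35, 0.6)
      clustered <- placed > 0L && runif(1) < params@clusterProb
      if (clustered) {
        anchor <- sample.int(placed, 1)
        dir <- runif(1, 0, 2 * pi)
        dist <- (bb[anchor] + bPx) * runif(1, 0.75, 0.98)
        ctr <- c(cy[anchor] + dist * sin(dir), cx[anchor] + dist * cos(dir))
        ok <- ctr[1] >= 1 && ctr[1] <= H && ctr[2] >= 1 && ctr[2] <= W
        cid <- clusterId[anchor]
      } else {
        # rejection sampling: keep isolated cells from touching anything
        ok <- FALSE
        for (att in seq_len(300)) {
          ctr <- c(runif(1, 1, H), runif(1, 1, W))
          if (placed == 0L) { ok <- TRUE; break }
          dmin <- sqrt((cy[seq_len(placed)] - ctr[1])^2 +
                       (cx[seq_len(placed)] - ctr[2])^2)
          if (all(dmin > aa[seq_len(placed)] + aPx + 3)) { ok <- TRUE; break }
        }
        cid <- placed + 1L
      }
      if (!ok) next
      placed <- placed + 1L
      cy[placed] <- ctr[1]; cx[placed] <- ctr[2]
      aa[placed] <- aPx; bb[placed] <- bPx
      clusterId[placed] <- if (clustered) cid else placed

      # rasterize: elliptical radius^2 within a bounding box
      pad <- ceiling(1.6 * aPx) + 1
      hs <- max(1, floor(ctr[1] - pad)):min(H, ceiling(ctr[1] + pad))
      ws <- max(1, floor(ctr[2] - pad)):min(W, ceiling(ctr[2] + pad))
      dy <- hs - ctr[1]; dx <- ws - ctr[2]
      DY <- matrix(dy, length(hs), length(ws))
      DX <- matrix(dx, length(hs), length(ws), byrow = TRUE)
      rot1 <- (DY * cos(theta) + DX * sin(theta)) / aPx
      rot2 <- (-DY * sin(theta) + DX * cos(theta)) / bPx
      r2 <- rot1^2 + rot2^2
      img[hs, ws] <- img[hs, ws] + amp * exp(-1.3 * r2) * (r2 <= 2.5)
      inside <- r2 <= 1
      sub <- bestR2[hs, ws]
      take <- inside & (r2 < sub)
      if (any(take)) {
        labSub <- label[hs, ws]
        labSub[take] <- placed
        label[hs, ws] <- labSub
        sub[take] <- r2[take]
        bestR2[hs, ws] <- sub
      }
    }

    # --- artifacts: bright sub-cell-sized dots, never in the mask
    set.seed(sbase + 4L)
    nArt <- rpois(1, params@artifactRate * areaMm2)
    for (i in seq_len(nArt)) {
      ctr <- c(runif(1, 1, H), runif(1, 1, W))
      r <- runif(1, 0.6, 1.4)
      amp <- runif(1, 0.45, 0.8)
      pad <- ceiling(3 * r)
      hs <- max(1, floor(ctr[1] - pad)):min(H, ceiling(ctr[1] + pad))
      ws <- max(1, floor(ctr[2] - pad)):min(W, ceiling(ctr[2] + pad))
      DY <- matrix(hs - ctr[1], length(hs), length(ws))
      DX <- matrix(ws - ctr[2], length(hs), length(ws), byrow = TRUE)
      r2 <- (DY^2 + DX^2) / r^2
      img[hs, ws] <- img[hs, ws] + amp * exp(-r2)
    }

    # --- noise, clipping, quantization to 16 bit
    set.seed(sbase + 5L)
    if (params@noiseSd > 0) img <- img + rnorm(H * W, 0, params@noiseSd)
    img <- pmin(pmax(img, 0), 1)
    maxI <- 2^16 - 1
    tile <- imageTile(round(img * maxI), bitDepth = 16L,
                      umPerPx = params@umPerPx)

    mask <- matrix(0L, H, W)
    mask[label > 0L] <- 1L
    regions <- regionTableFromLabels(label, params@umPerPx, placed)
    regions$cluster <- clusterId[regions$id]
    new("Scene", image = tile, mask = mask, regions = regions,
        trueDensity = placed / areaMm2)
  })
}

# Moment statistics of generator-truth (or measured) label matrices.
# Coordinates are 0-based; eccentricity comes from the moment-matched
# ellipse, e = sqrt(1 - lambda_minor/lambda_major). Pixels are treated as
# unit squares, so their own variance (1/12 per axis) enters the second
# central moments; this removes most of the small-axis discretization bias
# and gives single-pixel regions e = 0.
regionTableFromLabels <- function(label, umPerPx, nRegions = max(label)) {
  if (nRegions == 0L)
    return(data.frame(id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      area_um2 = numeric(0), eccentricity = numeric(0)))
  idx <- which(label > 0L)
  l <- label[idx]
  r <- (idx - 1L) %% nrow(label)     # 0-based row
  c <- (idx - 1L) %/% nrow(label)    # 0-based col
  n <- tabulate(l, nRegions)
  sr <- rowsum(r, l); sc <- rowsum(c, l)
  srr <- rowsum(r * r, l); scc <- rowsum(c * c, l); src <- rowsum(r * c, l)
  present <- sort(unique(l))
  cr <- cc <- rep(NA_real_, nRegions)
  cr[present] <- sr[, 1] / n[present]
  cc[present] <- sc[, 1] / n[present]
  mu20 <- mu02 <- mu11 <- rep(0, nRegions)
  mu20[present] <- srr[, 1] / n[present] - cr[present]^2 + 1 / 12
  mu02[present] <- scc[, 1] / n[present] - cc[present]^2 + 1 / 12
  mu11[present] <- src[, 1] / n[present] - cr[present] * cc[present]
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0)))
  data.frame(id = seq_len(nRegions), centroid_row = cr, centroid_col = cc,
             area_px = n, area_um2 = n * umPerPx^2, eccentricity = ecc)
}

#' Generate a mosaic of equally spaced scenes
#'
#' One scene per grid position, each with its own local target density, on a
#' physical grid whose pitch defaults to the tile extent (contiguous tiles)
#' or is derived from a stated region size -- e.g. an 8 x 8 grid covering a
#' 20 x 20 mm^2 region has a 2.5 mm pitch. Per-tile seeds are derived
#' deterministically from `params@seed`.
#'
#' @param gridRows,gridCols grid dimensions (positive).
#' @param densityField numeric matrix (`gridRows` x `gridCols`) of target
#'   densities, or a single value recycled; `NA` entries are an error.
#' @param params base [SceneParams-class]; `targetDensity` is overridden per
#'   tile.
#' @param regionMm optional physical extent (height, width) of the covered
#'   region in mm; the pitch is then `regionMm / grid`.
#' @return A [SceneMosaic-class].
#' @export
generateMosaic <- function(gridRows, gridCols, densityField, params,
                           regionMm = NULL) {
  stopifnot(gridRows >= 1, gridCols >= 1)
  if (length(densityField) == 1L)
    densityField <- matrix(densityField, gridRows, gridCols)
  densityField <- as.matrix(densityField)
  if (!identical(dim(densityField), c(as.integer(gridRows), as.integer(gridCols))))
    stop("densityField must be a ", gridRows, " x ", gridCols, " matrix")
  if (anyNA(densityField))
    stop("missing target density for grid cell(s): ",
         paste(which(is.na(densityField)), collapse = ", "))
  pitch <- if (is.null(regionMm)) {
    c(params@heightPx, params@widthPx) * params@umPerPx / 1000
  } else {
    if (length(regionMm) == 1L) regionMm <- c(regionMm, regionMm)
    regionMm / c(gridRows, gridCols)
  }
  scenes <- vector("list", gridRows * gridCols)
  layout <- data.frame(row = integer(0), col = integer(0),
                       x_mm = numeric(0), y_mm = numeric(0))
  k <- 0L
  for (r in seq_len(gridRows)) for (cc in seq_len(gridCols)) {
    k <- k + 1L
    p <- params
    p@targetDensity <- densityField[r, cc]
    p@seed <- params@seed + k
    scenes[[k]] <- generateScene(p)
    layout[k, ] <- list(r, cc, (cc - 1) * pitch[2], (r - 1) * pitch[1])
  }
  new("SceneMosaic", scenes = scenes, layout = layout,
      spacingMm = as.numeric(pitch))
}

#' Write a scene to disk
#'
#' The image is written as 16-bit grayscale TIFF, the mask as an 8-bit 0/255
#' PNG and the generator truth as a CSV sidecar.
#'
#' @param scene a [Scene-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxI <- 2^bitDepth(sceneImage(scene)) - 1
  pImg <- file.path(dir, paste0(prefix, "_image.tif"))
  pMask <- file.path(dir, paste0(prefix, "_mask.png"))
  pCsv <- file.path(dir, paste0(prefix, "_regions.csv"))
  tiff::writeTIFF(pixels(sceneImage(scene)) / maxI, pImg,
                  bits.per.sample = 16L)
  png::writePNG(sceneMask(scene) * 1.0, pMask)
  write.csv(sceneRegions(scene), pCsv, row.names = FALSE)
  invisible(c(image = pImg, mask = pMask, regions = pCsv))
}

#' Read a tile written by [writeScene()] or any grayscale TIFF/PNG
#' @param path image path (.tif/.tiff/.png).
#' @param umPerPx calibration to attach.
#' @param bitDepth native bit depth of the stored data.
#' @return An [ImageTile-class].
#' @export
readTile <- function(path, umPerPx = 0.5, bitDepth = 16L) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  imageTile(round(img * (2^bitDepth - 1)), bitDepth = as.integer(bitDepth),
            umPerPx = umPerPx)
}
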