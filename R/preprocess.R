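# CLAHE contrast normalization, paired random cropping and right-angle
# rotation/flip augmentation. Masks follow every geometric transform in
# lockstep with nearest-neighbour (exact) semantics; augmentation is a
# training-time operation only.

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-interpolated adaptive histogram equalization with clipping
#' (Zuiderveld's algorithm): the image is divided into a grid of contextual
#' tiles, each tile's histogram is clipped at `clipLimit` of its pixel
#' count with the excess redistributed evenly, the clipped cumulative
#' histograms define per-tile grey-level mappings, and every pixel is
#' mapped by bilinear interpolation between the four surrounding tile
#' mappings (so tile seams are invisible). `clipLimit` uses the normalized
#' convention: one histogram bin may hold at most `clipLimit` of a tile's
#' pixels before clipping; the default 0.01 with an 8 x 8 grid is the
#' common setting for microscopy. A 1 x 1 grid with a large clip limit
#' reduces to global histogram equalization; a constant image is returned
#' unchanged.
#'
#' @param tile an [ImageTile-class].
#' @param clipLimit normalized clip limit, > 0.
#' @param grid integer length 2, contextual tiles per dimension
#'   (rows, cols); the image must be at least one pixel per grid cell.
#' @param bins histogram bins.
#' @return An [ImageTile-class] with the same shape, calibration and bit
#'   depth; output is deterministic and spans at most the full bit range.
#' @examples
#' t0 <- imageTile(matrix(seq(0, 2000, length.out = 64 * 64), 64, 64))
#' t1 <- applyClahe(t0, grid = c(4, 4))
#' @export
applyClahe <- function(tile, clipLimit = 0.01, grid = c(8, 8), bins = 256L) {
  stopifnot(is(tile, "ImageTile"), clipLimit > 0, all(grid >= 1))
  px <- pixels(tile)
  if (nrow(px) < grid[1] || ncol(px) < grid[2])
    stop("tile (", nrow(px), " x ", ncol(px),
         ") is smaller than the CLAHE grid (", grid[1], " x ", grid[2], ")")
  maxI <- 2^bitDepth(tile) - 1
  out <- claheCore(px / maxI, ny = grid[1], nx = grid[2],
                   bins = as.integer(bins), clipLimit = clipLimit)
  imageTile(matrix(round(pmin(pmax(out, 0), 1) * maxI), nrow(px), ncol(px)),
            bitDepth = bitDepth(tile), umPerPx = umPerPx(tile))
}

# Vectorized CLAHE on a [0,1] matrix. Tiles may have non-integer nominal
# size H/ny x W/nx; pixel (r, c) contributes to tile (ceil(r*ny/H),
# ceil(c*nx/W)) and is mapped by bilinear interpolation between the
# mappings of the tiles whose centers surround it.
claheCore <- function(img, ny, nx, bins = 256L, clipLimit = 0.01) {
  H <- nrow(img); W <- ncol(img)
  gmin <- min(img); gmax <- max(img)
  if (gmax <= gmin) return(img)
  binOf <- function(v) pmin(bins - 1L, as.integer((v - gmin) /
                                                  (gmax - gmin) * bins)) + 1L
  bi <- matrix(binOf(img), H, W)
  th <- H / ny; tw <- W / nx
  tileRow <- pmin(ny, ceiling(seq_len(H) / th))
  tileCol <- pmin(nx, ceiling(seq_len(W) / tw))
  tileOf <- matrix(tileRow, H, W) + ny * (matrix(tileCol, H, W,
                                                 byrow = TRUE) - 1L)
  # per-tile clipped histograms -> grey-level mappings
  counts <- tabulate((tileOf - 1L) * bins + bi, ny * nx * bins)
  maps <- array(0, c(ny, nx, bins))
  npixTile <- tabulate(tileOf, ny * nx)
  for (t in seq_len(ny * nx)) {
    h <- counts[((t - 1L) * bins + 1L):(t * bins)]
    npix <- npixTile[t]
    clip <- max(1, clipLimit * npix)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip)
    inc <- excess %/% bins
    rem <- excess - inc * bins
    h <- h + inc
    if (rem > 0) {                 # spread the remainder at even steps
      step <- max(1, floor(bins / rem))
      i <- 1
      while (rem > 0 && i <= bins) {
        if (h[i] < clip) { h[i] <- h[i] + 1; rem <- rem - 1 }
        i <- i + step
      }
    }
    ty <- (t - 1L) %% ny + 1L; tx <- (t - 1L) %/% ny + 1L
    maps[ty, tx, ] <- gmin + (gmax - gmin) * cumsum(h) / npix
  }
  # bilinear interpolation between the four surrounding tile mappings
  tyc <- (seq_len(H) - 0.5) / th + 0.5
  txc <- (seq_len(W) - 0.5) / tw + 0.5
  y0 <- pmin(pmax(floor(tyc), 1), ny); y1 <- pmin(y0 + 1, ny)
  wy <- pmin(pmax(tyc - y0, 0), 1)
  x0 <- pmin(pmax(floor(txc), 1), nx); x1 <- pmin(x0 + 1, nx)
  wx <- pmin(pmax(txc - x0, 0), 1)
  Y0 <- matrix(y0, H, W); Y1 <- matrix(y1, H, W)
  WY <- matrix(wy, H, W)
  X0 <- matrix(x0, H, W, byrow = TRUE); X1 <- matrix(x1, H, W, byrow = TRUE)
  WX <- matrix(wx, H, W, byrow = TRUE)
  look <- function(Y, X) matrix(maps[cbind(as.vector(Y), as.vector(X),
                                           as.vector(bi))], H, W)
  (1 - WY) * ((1 - WX) * look(Y0, X0) + WX * look(Y0, X1)) +
    WY * ((1 - WX) * look(Y1, X0) + WX * look(Y1, X1))
}

#' Augmentation specification
#'
#' @param cropSizePx square crop size in pixels (the training protocol crops
#'   2048 x 2048 tiles to 512 x 512).
#' @param rotations subset of `c(0, 90, 180, 270)` degrees.
#' @param flips subset of `c("none", "horizontal", "vertical")`.
#' @param nCropsPerImage random crops drawn per source image.
#' @param seed integer seed, or `NA` to draw from the ambient RNG stream.
#' @return A list with class `"AugmentSpec"`.
#' @export
augmentSpec <- function(cropSizePx = 512L, rotations = c(0, 90, 180, 270),
                        flips = c("none", "horizontal", "vertical"),
                        nCropsPerImage = 1L, seed = NA_integer_) {
  stopifnot(cropSizePx >= 1, all(rotations %in% c(0, 90, 180, 270)),
            all(flips %in% c("none", "horizontal", "vertical")),
            nCropsPerImage >= 1)
  structure(list(cropSizePx = as.integer(cropSizePx),
                 rotations = rotations, flips = flips,
                 nCropsPerImage = as.integer(nCropsPerImage),
                 seed = as.integer(seed)),
            class = "AugmentSpec")
}

rot90mat <- function(m, deg) {
  switch(as.character(deg %% 360),
         "0" = m,
         "90" = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],   # 90 deg CCW
         "180" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         "270" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
         stop("rotation must be a multiple of 90 degrees"))
}

flipmat <- function(m, how) {
  switch(how,
         none = m,
         horizontal = m[, rev(seq_len(ncol(m))), drop = FALSE],
         vertical = m[rev(seq_len(nrow(m))), , drop = FALSE],
         stop("unknown flip: ", how))
}

#' Random co-registered crop of an image/mask pair
#'
#' The same offset, drawn uniformly over all valid positions, is applied to
#' both the tile and the mask.
#'
#' @param tile an [ImageTile-class].
#' @param mask integer 0/1 matrix co-registered with `tile`.
#' @param spec an [augmentSpec()]; if `spec$seed` is not `NA` the offset is
#'   drawn from a private stream seeded by it (deterministic per call).
#' @return list with elements `image` ([ImageTile-class]), `mask`, and
#'   `offset` (top-left 1-based row/col of the crop).
#' @export
randomCropPair <- function(tile, mask, spec) {
  px <- pixels(tile)
  stopifnot(identical(dim(px), dim(mask)))
  s <- spec$cropSizePx
  if (s > nrow(px) || s > ncol(px))
    stop("crop size ", s, " exceeds image dimensions ",
         nrow(px), " x ", ncol(px))
  draw <- function() c(sample.int(nrow(px) - s + 1L, 1L),
                       sample.int(ncol(px) - s + 1L, 1L))
  off <- if (!is.na(spec$seed)) withLocalSeed(spec$seed, draw()) else draw()
  rows <- off[1]:(off[1] + s - 1L); cols <- off[2]:(off[2] + s - 1L)
  list(image = imageTile(px[rows, cols, drop = FALSE], bitDepth(tile),
                         umPerPx(tile)),
       mask = mask[rows, cols, drop = FALSE], offset = off)
}

#' Expand an image/mask pair by crop, rotation and flip
#'
#' Draws `nCropsPerImage` random crops and applies every listed rotation and
#' flip to each, with the identical transform applied to image and mask, for
#' a total of `nCropsPerImage * |rotations| * |flips|` pairs. Rotations are
#' right angles only so binary masks stay exact; the foreground pixel count
#' is invariant under rotation and flip (not under crop). Test-time
#' pipelines must not call this (see [runPipeline()]).
#'
#' @inheritParams randomCropPair
#' @return list of pairs, each `list(image, mask, transform)` where
#'   `transform` records the crop offset, rotation and flip.
#' @export
augmentPair <- function(tile, mask, spec) {
  body <- function() {
    out <- vector("list", 0L)
    for (i in seq_len(spec$nCropsPerImage)) {
      cp <- randomCropPair(tile, mask,
                           augmentSpec(spec$cropSizePx, 0, "none", 1L))
      for (rot in spec$rotations) for (fl in spec$flips) {
        im <- flipmat(rot90mat(pixels(cp$image), rot), fl)
        mk <- flipmat(rot90mat(cp$mask, rot), fl)
        out[[length(out) + 1L]] <- list(
          image = imageTile(im, bitDepth(tile), umPerPx(tile)), mask = mk,
          transform = list(offset = cp$offset, rotation = rot, flip = fl))
      }
    }
    out
  }
  if (!is.na(spec$seed)) withLocalSeed(spec$seed, body()) else body()
}
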