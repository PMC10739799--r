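# Independent scalar-loop oracles used across the suite. These deliberately
# avoid the package's vectorized/compiled code paths.

# pixel-loop confusion counts
loopConfusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0; g <- gt[i, j] > 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && g) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# scalar-loop channel descriptor (per-channel spatial mean) of an
# (H, W, C) array
loopChannelMean <- function(x) {
  d <- dim(x)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + x[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

# scalar-loop CLAHE (clipped tile histograms, even redistribution, CDF
# mappings, bilinear interpolation between tile centres) on a [0,1] matrix
loopClahe <- function(img, ny, nx, bins = 256L, clipLimit = 0.01) {
  H <- nrow(img); W <- ncol(img)
  gmin <- min(img); gmax <- max(img)
  if (gmax <= gmin) return(img)
  binOf <- function(v) min(bins - 1L, as.integer((v - gmin) /
                                                 (gmax - gmin) * bins)) + 1L
  th <- H / ny; tw <- W / nx
  maps <- array(0, c(ny, nx, bins))
  for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
    h <- numeric(bins); npix <- 0
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (min(ny, ceiling(r / th)) == ty && min(nx, ceiling(c / tw)) == tx) {
        b <- binOf(img[r, c]); h[b] <- h[b] + 1; npix <- npix + 1
      }
    }
    clip <- max(1, clipLimit * npix)
    excess <- 0
    for (b in seq_len(bins)) if (h[b] > clip) {
      excess <- excess + h[b] - clip; h[b] <- clip
    }
    inc <- excess %/% bins; rem <- excess - inc * bins
    h <- h + inc
    if (rem > 0) {
      step <- max(1, floor(bins / rem)); i <- 1
      while (rem > 0 && i <= bins) {
        if (h[i] < clip) { h[i] <- h[i] + 1; rem <- rem - 1 }
        i <- i + step
      }
    }
    cdf <- 0
    for (b in seq_len(bins)) {
      cdf <- cdf + h[b]
      maps[ty, tx, b] <- gmin + (gmax - gmin) * cdf / npix
    }
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    tyc <- (r - 0.5) / th + 0.5; txc <- (c - 0.5) / tw + 0.5
    y0 <- min(max(floor(tyc), 1), ny); y1 <- min(y0 + 1, ny)
    wy <- min(max(tyc - y0, 0), 1)
    x0 <- min(max(floor(txc), 1), nx); x1 <- min(x0 + 1, nx)
    wx <- min(max(txc - x0, 0), 1)
    b <- binOf(img[r, c])
    out[r, c] <- (1 - wy) * ((1 - wx) * maps[y0, x0, b] + wx * maps[y0, x1, b]) +
      wy * ((1 - wx) * maps[y1, x0, b] + wx * maps[y1, x1, b])
  }
  out
}

# small synthetic scene shared by model/training tests
tinyScene <- function(seed, size = 64L, density = 1800, cluster = 0.2) {
  generateScene(sceneParams(widthPx = size, heightPx = size, umPerPx = 1,
                            targetDensity = density, seed = seed,
                            vesselCount = 1L, clusterProb = cluster))
}

tinySample <- function(seed, case, ...) {
  sc <- tinyScene(seed, ...)
  list(image = sceneImage(sc), mask = sceneMask(sc), case = case)
}

# gradient-tree leaf access used by the finite-difference checks
getLeaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
setLeaf <- function(p, path, v) {
  if (length(path) == 1) { p[[path[[1]]]] <- v; return(p) }
  p[[path[[1]]]] <- setLeaf(p[[path[[1]]]], path[-1], v)
  p
}
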