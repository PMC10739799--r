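# Semi-automated ground-truth production: (1) sectional adaptive
# thresholding separates bright cells from a spatially varying background,
# (2) a baseline U-Net trained on those initial masks produces rough
# predictions for subsequent manual refinement. The manual refinement step
# itself is out of computational scope; masks are read and written as
# editable 0/255 PNGs.

#' A sectional threshold grid
#'
#' Rectangular sections exactly tiling the image, each with its own
#' intensity threshold (on the tile's native scale).
#'
#' @param rowBreaks,colBreaks increasing integer boundaries starting at 0
#'   and ending at the image height/width; section i spans
#'   `(breaks[i], breaks[i+1]]`.
#' @param thresholds numeric matrix, one threshold per section
#'   (`length(rowBreaks)-1` x `length(colBreaks)-1`).
#' @return list with class `"SectionGrid"`.
#' @export
sectionGrid <- function(rowBreaks, colBreaks, thresholds) {
  stopifnot(!is.unsorted(rowBreaks, strictly = TRUE),
            !is.unsorted(colBreaks, strictly = TRUE),
            rowBreaks[1] == 0, colBreaks[1] == 0)
  thresholds <- as.matrix(thresholds)
  if (!identical(dim(thresholds),
                 c(length(rowBreaks) - 1L, length(colBreaks) - 1L)))
    stop("thresholds must be (rows-1) x (cols-1) of the break vectors")
  structure(list(rowBreaks = as.integer(rowBreaks),
                 colBreaks = as.integer(colBreaks), thresholds = thresholds),
            class = "SectionGrid")
}

#' Sectional adaptive thresholding
#'
#' A pixel is foreground iff its intensity strictly exceeds its section's
#' threshold. Raising any section's threshold can only remove foreground.
#'
#' @param tile an [ImageTile-class].
#' @param grid a [sectionGrid()] whose bounds match the tile.
#' @return integer 0/1 mask.
#' @export
sectionalThreshold <- function(tile, grid) {
  px <- pixels(tile)
  if (max(grid$rowBreaks) != nrow(px) || max(grid$colBreaks) != ncol(px))
    stop("section bounds (", max(grid$rowBreaks), " x ",
         max(grid$colBreaks), ") do not match the tile (",
         nrow(px), " x ", ncol(px), ")")
  mask <- matrix(0L, nrow(px), ncol(px))
  nr <- length(grid$rowBreaks) - 1L
  nc <- length(grid$colBreaks) - 1L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- (grid$rowBreaks[i] + 1L):grid$rowBreaks[i + 1L]
    cs <- (grid$colBreaks[j] + 1L):grid$colBreaks[j + 1L]
    mask[rs, cs][px[rs, cs] > grid$thresholds[i, j]] <- 1L
  }
  mask
}

#' Automatic per-section thresholds (Otsu)
#'
#' Reproducible surrogate for manually chosen section thresholds: the image
#' is divided into an even grid and each section's threshold is computed
#' from its own histogram by Otsu's method. A constant section gets its own
#' value as threshold, yielding empty foreground there.
#'
#' @param tile an [ImageTile-class].
#' @param gridDims integer length 2: sections per dimension (rows, cols).
#' @return a [sectionGrid()].
#' @export
autoSectionThresholds <- function(tile, gridDims = c(4, 4)) {
  stopifnot(all(gridDims >= 1))
  px <- pixels(tile)
  maxI <- 2^bitDepth(tile) - 1
  rowBreaks <- round(seq(0, nrow(px), length.out = gridDims[1] + 1))
  colBreaks <- round(seq(0, ncol(px), length.out = gridDims[2] + 1))
  th <- matrix(0, gridDims[1], gridDims[2])
  for (i in seq_len(gridDims[1])) for (j in seq_len(gridDims[2])) {
    sec <- px[(rowBreaks[i] + 1):rowBreaks[i + 1],
              (colBreaks[j] + 1):colBreaks[j + 1]]
    th[i, j] <- if (diff(range(sec)) == 0) sec[1]
      else EBImage::otsu(EBImage::Image(sec / maxI),
                         levels = 2^bitDepth(tile)) * maxI
  }
  sectionGrid(rowBreaks, colBreaks, th)
}

#' Rough masks from a trained baseline model
#'
#' Binarizes the baseline's probability maps for subsequent manual
#' refinement.
#'
#' @param model a trained model handle (see [trainModel()]).
#' @param tiles an [ImageTile-class] or list of them.
#' @param threshold binarization threshold; at the default 0.5 the mask is
#'   exactly the pixelwise comparison p > 0.5.
#' @return 0/1 mask matrix, or a list of them.
#' @export
bootstrapPredict <- function(model, tiles, threshold = 0.5) {
  if (!isTRUE(model$trained))
    stop("model has not been trained; run trainModel() first")
  probs <- predictProb(model, tiles)
  if (is.list(probs)) lapply(probs, binarizeProb, threshold = threshold)
  else binarizeProb(probs, threshold)
}

#' Read / write editable mask PNGs
#'
#' Masks travel as 8-bit 0/255 PNGs so external editors can perform the
#' manual refinement pass.
#'
#' @param mask 0/1 integer matrix.
#' @param path PNG path.
#' @return `writeMaskPng` the path invisibly; `readMaskPng` a 0/1 matrix.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  out <- matrix(0L, nrow(img), ncol(img))
  out[img > 0.5] <- 1L
  out
}
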