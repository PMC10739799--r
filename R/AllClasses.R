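#' Parameters of a synthetic microscopy scene
#'
#' Describes a simulated MBFM-like field: geometry and calibration, target
#' goblet-cell density, the cell size/shape distribution, clustering
#' behaviour, vessel shadows, bright non-cell artifacts, background gradient
#' and noise. Equal seeds give bit-identical scenes.
#'
#' @slot widthPx,heightPx tile size in pixels.
#' @slot umPerPx pixel calibration, micrometres per pixel.
#' @slot targetDensity target cell density in cells/mm^2.
#' @slot cellAreaMean,cellAreaSd cell area distribution in um^2.
#' @slot cellEccRange eccentricity range, numeric length 2 within [0, 1).
#' @slot clusterProb probability that a cell is placed touching an earlier
#'   cell (forming a cluster) instead of independently.
#' @slot vesselCount number of dark curvilinear vessel shadows.
#' @slot vesselShadowDepth maximum fractional darkening under a vessel, [0,1].
#' @slot artifactRate bright sub-cell-sized non-cell objects per mm^2.
#' @slot noiseSd additive Gaussian noise sd on the normalized [0,1] scale.
#' @slot backgroundGradientAmp amplitude of the smooth background gradient.
#' @slot seed integer seed of the scene's private random stream.
#' @exportClass SceneParams
setClass("SceneParams", representation(
  widthPx = "integer", heightPx = "integer", umPerPx = "numeric",
  targetDensity = "numeric", cellAreaMean = "numeric", cellAreaSd = "numeric",
  cellEccRange = "numeric", clusterProb = "numeric", vesselCount = "integer",
  vesselShadowDepth = "numeric", artifactRate = "numeric", noiseSd = "numeric",
  backgroundGradientAmp = "numeric", seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "widthPx and heightPx must be positive")
  if (!is.finite(object@umPerPx) || object@umPerPx <= 0)
    msg <- c(msg, "umPerPx must be a positive real")
  if (object@targetDensity < 0) msg <- c(msg, "targetDensity must be >= 0")
  if (object@cellAreaMean <= 0 || object@cellAreaSd <= 0)
    msg <- c(msg, "cell area mean and sd must be > 0")
  if (length(object@cellEccRange) != 2L ||
      any(object@cellEccRange < 0) || any(object@cellEccRange >= 1) ||
      diff(object@cellEccRange) < 0)
    msg <- c(msg, "cellEccRange must be an ordered interval within [0, 1)")
  for (p in c("clusterProb", "vesselShadowDepth"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, paste(p, "must lie in [0, 1]"))
  if (object@vesselCount < 0L) msg <- c(msg, "vesselCount must be >= 0")
  if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@backgroundGradientAmp < 0)
    msg <- c(msg, "backgroundGradientAmp must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct scene parameters
#'
#' Defaults emulate the MBFM goblet-cell imagery the pipeline targets:
#' 2048x2048 tiles, bright roundish cells of a few tens of um^2 at
#' 1000--2400 cells/mm^2 (default 1500), distributed individually and in
#' touching clusters over a smoothly varying background shadowed by dark
#' vessel-like structures, with additive noise and occasional small bright
#' non-cell artifacts. The field of view per tile is not fixed by the
#' modality, so `umPerPx` is a free calibration parameter.
#'
#' @param widthPx,heightPx tile size in pixels.
#' @param umPerPx micrometres per pixel.
#' @param targetDensity target density, cells/mm^2.
#' @param cellAreaMean,cellAreaSd cell area distribution (um^2).
#' @param cellEccRange eccentricity interval within [0, 1).
#' @param clusterProb probability a cell joins a touching cluster.
#' @param vesselCount number of vessel shadows.
#' @param vesselShadowDepth maximum fractional darkening, [0, 1].
#' @param artifactRate bright artifacts per mm^2.
#' @param noiseSd additive noise sd (normalized intensity units).
#' @param backgroundGradientAmp background gradient amplitude.
#' @param seed integer seed.
#' @return A [SceneParams-class] object.
#' @examples
#' p <- sceneParams(widthPx = 128, heightPx = 128, seed = 1)
#' @export
sceneParams <- function(widthPx = 2048L, heightPx = 2048L, umPerPx = 0.5,
                        targetDensity = 1500, cellAreaMean = 80,
                        cellAreaSd = 20, cellEccRange = c(0, 0.7),
                        clusterProb = 0.3, vesselCount = 4L,
                        vesselShadowDepth = 0.4, artifactRate = 10,
                        noiseSd = 0.02, backgroundGradientAmp = 0.15,
                        seed = 1L) {
  new("SceneParams", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), umPerPx = umPerPx,
      targetDensity = targetDensity, cellAreaMean = cellAreaMean,
      cellAreaSd = cellAreaSd, cellEccRange = as.numeric(cellEccRange),
      clusterProb = clusterProb, vesselCount = as.integer(vesselCount),
      vesselShadowDepth = vesselShadowDepth, artifactRate = artifactRate,
      noiseSd = noiseSd, backgroundGradientAmp = backgroundGradientAmp,
      seed = as.integer(seed))
}

#' A calibrated grayscale microscopy tile
#'
#' Intensities are stored on the native integer scale of the tile's bit
#' depth, i.e. within [0, 2^bitDepth - 1].
#'
#' @slot pixels numeric matrix (height x width) of intensities.
#' @slot bitDepth 8L or 16L.
#' @slot umPerPx micrometres per pixel.
#' @exportClass ImageTile
setClass("ImageTile", representation(
  pixels = "matrix", bitDepth = "integer", umPerPx = "numeric"
))

setValidity("ImageTile", function(object) {
  msg <- character()
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (!is.finite(object@umPerPx) || object@umPerPx <= 0)
    msg <- c(msg, "umPerPx must be positive")
  px <- object@pixels
  if (!is.numeric(px)) msg <- c(msg, "pixels must be numeric")
  else if (anyNA(px) || min(px) < 0 || max(px) > 2^object@bitDepth - 1)
    msg <- c(msg, "pixel intensities must lie in [0, 2^bitDepth - 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an image tile
#' @param pixels numeric matrix (height x width).
#' @param bitDepth 8 or 16.
#' @param umPerPx micrometres per pixel.
#' @return An [ImageTile-class].
#' @export
imageTile <- function(pixels, bitDepth = 16L, umPerPx = 0.5) {
  new("ImageTile", pixels = pixels, bitDepth = as.integer(bitDepth),
      umPerPx = umPerPx)
}

#' A synthetic scene: tile, exact mask and generator-truth regions
#'
#' @slot image the rendered [ImageTile-class].
#' @slot mask integer matrix of 0/1 ground-truth labels, co-registered with
#'   the image; the union of the generator-truth region pixel sets.
#' @slot regions data.frame with one row per placed cell: `id`,
#'   `centroid_row`, `centroid_col` (0-based), `area_px`, `area_um2`,
#'   `eccentricity`, `cluster`.
#' @slot trueDensity placed cells divided by physical area, cells/mm^2.
#' @exportClass Scene
setClass("Scene", representation(
  image = "ImageTile", mask = "matrix", regions = "data.frame",
  trueDensity = "numeric"
))

setValidity("Scene", function(object) {
  msg <- character()
  if (!identical(dim(object@image@pixels), dim(object@mask)))
    msg <- c(msg, "mask and image dimensions differ")
  if (!all(object@mask %in% c(0L, 1L))) msg <- c(msg, "mask must be 0/1")
  if (object@trueDensity < 0) msg <- c(msg, "trueDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A mosaic of equally spaced scenes on a physical grid
#'
#' @slot scenes list of [Scene-class] objects in row-major grid order.
#' @slot layout data.frame with `row`, `col` (1-based grid position) and
#'   `x_mm`, `y_mm` (tile top-left measured from the mosaic top-left).
#' @slot spacingMm numeric length 2, (row pitch, column pitch) in mm.
#' @exportClass SceneMosaic
setClass("SceneMosaic", representation(
  scenes = "list", layout = "data.frame", spacingMm = "numeric"
))

#' A grid of per-tile goblet-cell densities over a mosaic
#'
#' @slot densities matrix (grid rows x grid cols) of densities, cells/mm^2;
#'   `NA` marks missing tiles.
#' @slot spacingMm physical pitch of the grid, mm (row, col).
#' @slot counts matrix of per-tile region counts.
#' @slot tileAreaMm2 physical area of one tile, mm^2.
#' @exportClass DensityMap
setClass("DensityMap", representation(
  densities = "matrix", spacingMm = "numeric", counts = "matrix",
  tileAreaMm2 = "numeric"
))

setValidity("DensityMap", function(object) {
  d <- object@densities
  if (any(d[!is.na(d)] < 0)) "densities must be >= 0" else TRUE
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf("SceneParams: %d x %d px @ %.3g um/px, target %.5g cells/mm^2\n",
              object@widthPx, object@heightPx, object@umPerPx,
              object@targetDensity))
  cat(sprintf("  cell area %.3g +/- %.3g um^2, ecc [%.2f, %.2f], cluster p %.2f\n",
              object@cellAreaMean, object@cellAreaSd, object@cellEccRange[1],
              object@cellEccRange[2], object@clusterProb))
  cat(sprintf("  %d vessels (depth %.2f), %.3g artifacts/mm^2, noise %.3g, seed %d\n",
              object@vesselCount, object@vesselShadowDepth,
              object@artifactRate, object@noiseSd, object@seed))
})

setMethod("show", "ImageTile", function(object) {
  cat(sprintf("ImageTile: %d x %d px, %d-bit, %.3g um/px, range [%.5g, %.5g]\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              object@umPerPx, min(object@pixels), max(object@pixels)))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d x %d px, %d cells, true density %.5g cells/mm^2\n",
              nrow(object@mask), ncol(object@mask), nrow(object@regions),
              object@trueDensity))
})

setMethod("show", "SceneMosaic", function(object) {
  r <- max(object@layout$row); c <- max(object@layout$col)
  cat(sprintf("SceneMosaic: %d x %d tiles, pitch %.3g x %.3g mm\n",
              r, c, object@spacingMm[1], object@spacingMm[2]))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d x %d tiles at %.3g x %.3g mm pitch\n",
              nrow(object@densities), ncol(object@densities),
              object@spacingMm[1], object@spacingMm[2]))
  cat(sprintf("  densities %.4g - %.4g cells/mm^2 (%d missing)\n",
              suppressWarnings(min(object@densities, na.rm = TRUE)),
              suppressWarnings(max(object@densities, na.rm = TRUE)),
              sum(is.na(object@densities))))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for the core classes
#'
#' @param x an object of the documented classes.
#' @return `pixels()` the intensity matrix; `bitDepth()` and `umPerPx()` the
#'   tile metadata; `sceneImage()`, `sceneMask()`, `sceneRegions()` and
#'   `trueDensity()` the scene components; `densities()` and `spacingMm()`
#'   the density-map grid and pitch; `mosaicScenes()` and `mosaicLayout()`
#'   the mosaic components.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ImageTile", function(x) x@pixels)
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setMethod("bitDepth", "ImageTile", function(x) x@bitDepth)
#' @rdname accessors
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))
#' @rdname accessors
#' @export
setMethod("umPerPx", "ImageTile", function(x) x@umPerPx)
#' @rdname accessors
#' @export
setMethod("umPerPx", "Scene", function(x) x@image@umPerPx)
#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setMethod("sceneImage", "Scene", function(x) x@image)
#' @rdname accessors
#' @export
setGeneric("sceneMask", function(x) standardGeneric("sceneMask"))
#' @rdname accessors
#' @export
setMethod("sceneMask", "Scene", function(x) x@mask)
#' @rdname accessors
#' @export
setGeneric("sceneRegions", function(x) standardGeneric("sceneRegions"))
#' @rdname accessors
#' @export
setMethod("sceneRegions", "Scene", function(x) x@regions)
#' @rdname accessors
#' @export
setGeneric("trueDensity", function(x) standardGeneric("trueDensity"))
#' @rdname accessors
#' @export
setMethod("trueDensity", "Scene", function(x) x@trueDensity)
#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
#' @rdname accessors
#' @export
setMethod("densities", "DensityMap", function(x) x@densities)
#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setMethod("spacingMm", "DensityMap", function(x) x@spacingMm)
#' @rdname accessors
#' @export
setMethod("spacingMm", "SceneMosaic", function(x) x@spacingMm)
#' @rdname accessors
#' @export
setGeneric("mosaicScenes", function(x) standardGeneric("mosaicScenes"))
#' @rdname accessors
#' @export
setMethod("mosaicScenes", "SceneMosaic", function(x) x@scenes)
#' @rdname accessors
#' @export
setGeneric("mosaicLayout", function(x) standardGeneric("mosaicLayout"))
#' @rdname accessors
#' @export
setMethod("mosaicLayout", "SceneMosaic", function(x) x@layout)
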