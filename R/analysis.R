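# Downstream goblet-cell morphometry: binarization, 8-connected region
# extraction with moment statistics, density estimation, mosaic density
# maps, agreement with manual counts and longitudinal comparisons.

#' Binarize a probability map
#' @param prob numeric matrix with values in [0, 1].
#' @param threshold scalar in [0, 1]; a pixel is foreground iff p > threshold.
#' @return integer 0/1 matrix.
#' @export
binarizeProb <- function(prob, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- matrix(0L, nrow(prob), ncol(prob))
  out[prob > threshold] <- 1L
  out
}

#' Extract segmented cell regions from a binary mask
#'
#' Labels 8-connected components (so touching cells -- including diagonal
#' contact -- merge into one region, reproducing the aggregated-cell
#' undercount of connected-component counting) and computes per-region
#' moment statistics: 0-based centroid, pixel and physical area, and the
#' eccentricity of the moment-matched ellipse,
#' e = sqrt(1 - lambda_minor/lambda_major); single-pixel regions have e = 0.
#'
#' @param mask 0/1 matrix.
#' @param umPerPx pixel calibration.
#' @param minAreaPx regions smaller than this many pixels are discarded
#'   (noise suppression); 0 disables.
#' @return data.frame with columns `id`, `centroid_row`, `centroid_col`,
#'   `area_px`, `area_um2`, `eccentricity`.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
#' extractRegions(m, umPerPx = 1, minAreaPx = 0)
#' @export
extractRegions <- function(mask, umPerPx, minAreaPx = 5) {
  stopifnot(all(mask %in% c(0, 1)), umPerPx > 0)
  lab <- cc_label8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  tab <- regionTableFromLabels(lab, umPerPx)
  tab <- tab[tab$area_px >= minAreaPx, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Cell density from a region table
#' @param regions data.frame as from [extractRegions()].
#' @param fieldAreaMm2 physical area of the analysed field, mm^2, > 0.
#' @return density in cells/mm^2.
#' @export
gcDensity <- function(regions, fieldAreaMm2) {
  if (fieldAreaMm2 <= 0) stop("fieldAreaMm2 must be positive")
  nrow(regions) / fieldAreaMm2
}

#' Per-tile density map over a mosaic
#'
#' Counts segmented regions per tile -- from supplied probability maps
#' (binarized at `threshold`) or, when `probs` is `NULL`, from the scenes'
#' own masks -- and places the densities on the mosaic's physical grid.
#'
#' @param mosaic a [SceneMosaic-class].
#' @param probs optional list of probability matrices, one per tile in
#'   mosaic order; `NULL` entries are recorded as missing tiles.
#' @param threshold binarization threshold for `probs`.
#' @param minAreaPx forwarded to [extractRegions()].
#' @return A [DensityMap-class].
#' @export
densityMap <- function(mosaic, probs = NULL, threshold = 0.5, minAreaPx = 5) {
  lay <- mosaicLayout(mosaic)
  scenes <- mosaicScenes(mosaic)
  R <- max(lay$row); C <- max(lay$col)
  dens <- cnt <- matrix(NA_real_, R, C)
  areas <- vapply(scenes, function(s)
    tileAreaMm2(ncol(sceneMask(s)), nrow(sceneMask(s)), umPerPx(s)),
    numeric(1))
  for (k in seq_len(nrow(lay))) {
    m <- if (is.null(probs)) sceneMask(scenes[[k]])
         else if (is.null(probs[[k]])) NULL
         else binarizeProb(probs[[k]], threshold)
    if (is.null(m)) {
      warning("missing prediction for tile ", k, " (grid ", lay$row[k], ",",
              lay$col[k], "); recorded as a gap")
      next
    }
    reg <- extractRegions(m, umPerPx(scenes[[k]]), minAreaPx)
    cnt[lay$row[k], lay$col[k]] <- nrow(reg)
    dens[lay$row[k], lay$col[k]] <- gcDensity(reg, areas[k])
  }
  new("DensityMap", densities = dens, spacingMm = spacingMm(mosaic),
      counts = cnt, tileAreaMm2 = areas[1])
}

#' Render a density map as a colour overlay PNG
#'
#' The density grid is expanded to the mosaic image size, mapped through a
#' dark-blue-to-yellow colormap and alpha-blended over the stitched
#' grayscale mosaic.
#'
#' @param dmap a [DensityMap-class].
#' @param mosaic the matching [SceneMosaic-class].
#' @param file output PNG path.
#' @param alpha overlay opacity in [0, 1].
#' @param zlim colormap bounds (cells/mm^2); defaults to the data range.
#' @return Invisibly, `file`.
#' @export
renderDensityOverlay <- function(dmap, mosaic, file, alpha = 0.4,
                                 zlim = NULL) {
  lay <- mosaicLayout(mosaic)
  scenes <- mosaicScenes(mosaic)
  th <- nrow(sceneMask(scenes[[1]])); tw <- ncol(sceneMask(scenes[[1]]))
  R <- max(lay$row); C <- max(lay$col)
  big <- matrix(0, R * th, C * tw)
  for (k in seq_len(nrow(lay))) {
    tile <- sceneImage(scenes[[k]])
    big[(lay$row[k] - 1) * th + seq_len(th),
        (lay$col[k] - 1) * tw + seq_len(tw)] <-
      pixels(tile) / (2^bitDepth(tile) - 1)
  }
  d <- densities(dmap)
  if (is.null(zlim)) zlim <- range(d, na.rm = TRUE)
  if (diff(zlim) == 0) zlim[2] <- zlim[1] + 1
  z <- (d - zlim[1]) / diff(zlim)
  z <- pmin(pmax(z, 0), 1)
  zbig <- z[rep(seq_len(R), each = th), rep(seq_len(C), each = tw)]
  ok <- !is.na(zbig)
  rgb <- array(rep(big, 3), c(dim(big), 3))
  # dark blue -> yellow ramp
  rr <- zbig; gg <- 0.2 + 0.8 * zbig; bb <- 0.6 * (1 - zbig)
  rgb[, , 1][ok] <- (1 - alpha) * big[ok] + alpha * rr[ok]
  rgb[, , 2][ok] <- (1 - alpha) * big[ok] + alpha * gg[ok]
  rgb[, , 3][ok] <- (1 - alpha) * big[ok] + alpha * bb[ok]
  png::writePNG(pmin(pmax(rgb, 0), 1), file)
  invisible(file)
}

#' Agreement between automated and manual density estimates
#'
#' @param auto,manual paired density vectors (same length, n >= 3).
#' @return list with `r` (Pearson correlation), `ratioMean` (mean of
#'   auto/manual), and `limits` (2.5th and 97.5th percentiles of the
#'   relative error (auto - manual)/manual, as fractions).
#' @export
densityAgreement <- function(auto, manual) {
  stopifnot(length(auto) == length(manual), length(auto) >= 3)
  if (sd(auto) == 0 || sd(manual) == 0)
    stop("zero-variance input: correlation undefined")
  relErr <- (auto - manual) / manual
  list(r = cor(auto, manual),
       ratioMean = mean(auto / manual),
       limits = unname(quantile(relErr, c(0.025, 0.975), type = 7)))
}

#' Per-timepoint density and size summaries
#'
#' Longitudinal comparison of goblet-cell populations, e.g. before damage
#' and at recovery timepoints: per group mean +/- sd of the per-tile density
#' and of the pooled cell areas.
#'
#' @param tiles data.frame with columns `timepoint`, `tile`, `density`.
#' @param regions data.frame with columns `timepoint`, `area_um2`.
#' @return data.frame with one row per timepoint: `timepoint`, `n_tiles`,
#'   `density_mean`, `density_sd`, `n_cells`, `size_mean`, `size_sd`; sd is
#'   `NA` for single-member groups; empty groups are flagged with a warning.
#' @export
compareTimepoints <- function(tiles, regions) {
  tps <- unique(c(as.character(tiles$timepoint),
                  as.character(regions$timepoint)))
  out <- lapply(tps, function(tp) {
    d <- tiles$density[tiles$timepoint == tp]
    a <- regions$area_um2[regions$timepoint == tp]
    if (!length(d)) warning("timepoint ", tp, " has no tiles")
    data.frame(timepoint = tp, n_tiles = length(d),
               density_mean = if (length(d)) mean(d) else NA_real_,
               density_sd = if (length(d) > 1) sd(d) else NA_real_,
               n_cells = length(a),
               size_mean = if (length(a)) mean(a) else NA_real_,
               size_sd = if (length(a) > 1) sd(a) else NA_real_)
  })
  do.call(rbind, out)
}
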