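# Pixel-level segmentation metrics: confusion counts, the ratio metrics
# derived from them, precision-recall curves with area under the curve, and
# repeated-run aggregation.

#' Pixel-level confusion counts between a predicted and a reference mask
#'
#' @param pred,gt co-registered 0/1 matrices of identical shape.
#' @return list with integer fields `tp`, `fp`, `tn`, `fn` summing to the
#'   pixel count.
#' @examples
#' confusionCounts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusionCounts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"))
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  list(tp = tp, fp = fp, tn = length(p) - tp - fp - fn, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' Computes recall (true positive rate) TP/(TP+FN), precision TP/(TP+FP),
#' false positive rate 1 - TN/(TN+FP), intersection-over-union
#' TP/(TP+FP+FN) and the Dice coefficient 2TP/(2TP+FP+FN). The Dice and IoU
#' always satisfy dice = 2 iou/(1 + iou). When both masks are empty
#' (TP+FP+FN = 0) the overlap metrics are 1 by convention and the report is
#' flagged `degenerate`.
#'
#' @param counts a list as returned by [confusionCounts()].
#' @return data.frame with one row: `dice`, `iou`, `recall`, `precision`,
#'   `fpr`, `degenerate`.
#' @export
metricsFromCounts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  degen <- (tp + fp + fn) == 0
  div <- function(num, den, empty = 1) if (den == 0) empty else num / den
  data.frame(
    dice = if (degen) 1 else 2 * tp / (2 * tp + fp + fn),
    iou = if (degen) 1 else tp / (tp + fp + fn),
    recall = div(tp, tp + fn),
    precision = div(tp, tp + fp),
    fpr = div(fp, tn + fp, empty = 0),
    degenerate = degen
  )
}

#' Precision-recall curve and area under it
#'
#' Sweeps binarization thresholds over a probability map: at each threshold
#' t pixels with p >= t are predicted foreground (so threshold 0 yields
#' recall 1), and one (recall, precision) point is recorded. The area under
#' the curve (AP) is the trapezoidal integral of precision over recall.
#' True negatives play no role.
#'
#' @param prob numeric matrix of per-pixel foreground probabilities in
#'   [0, 1].
#' @param gt co-registered 0/1 reference mask.
#' @param thresholds increasing thresholds in [0, 1]; default 256 evenly
#'   spaced values.
#' @return list with `curve` (data.frame threshold/recall/precision), `ap`,
#'   and `gtEmpty` flag (precision is undefined beyond the threshold
#'   extremes when the reference has no foreground).
#' @export
prCurve <- function(prob, gt, thresholds = seq(0, 1, length.out = 256)) {
  if (!identical(dim(prob), dim(gt))) stop("shape mismatch")
  stopifnot(!is.unsorted(thresholds), all(thresholds >= 0 & thresholds <= 1))
  g <- gt > 0
  npos <- sum(g)
  rec <- prec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    p <- prob >= thresholds[i]
    tp <- sum(p & g)
    rec[i] <- if (npos == 0) 1 else tp / npos
    prec[i] <- if (sum(p) == 0) 1 else tp / sum(p)
  }
  # anchor at recall 0 (precision of the strictest threshold) so the
  # integral spans the full recall axis; a perfect 0/1 prediction then
  # scores ap = 1 instead of a degenerate zero-width curve
  ord <- rev(seq_along(thresholds))   # strictest threshold first;
  recA <- c(0, rec[ord])              # recall is then non-decreasing
  precA <- c(prec[ord][1], prec[ord])
  ap <- sum(diff(recA) * (precA[-1] + precA[-length(precA)]) / 2)
  list(curve = data.frame(threshold = thresholds, recall = rec,
                          precision = prec),
       ap = ap, gtEmpty = npos == 0)
}

#' Aggregate repeated evaluation runs
#'
#' @param reports list (length >= 2) of one-row data.frames as returned by
#'   [metricsFromCounts()], optionally with an `ap` column.
#' @return data.frame with one row per metric: `metric`, `mean`, `sd`
#'   (sample standard deviation).
#' @export
aggregateRuns <- function(reports) {
  stopifnot(length(reports) >= 2)
  tab <- do.call(rbind, reports)
  num <- vapply(tab, is.numeric, logical(1))
  cols <- names(tab)[num]
  data.frame(metric = cols,
             mean = vapply(cols, function(cl) mean(tab[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd(tab[[cl]]), numeric(1)),
             row.names = NULL)
}
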