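# Segmentation losses: soft dice, focal, binary cross-entropy and the
# compound dice+focal objective used to train the attention network. Each
# loss has a matching analytic gradient used by the training loop.

#' Loss configuration
#'
#' The compound objective is `diceWeight * dice + focalWeight * focal`; the
#' protocol default is 0.7/0.3. Focal hyperparameters default to gamma = 2,
#' alpha = 0.25 (the standard focal-loss settings).
#'
#' @param diceWeight,focalWeight non-negative weights (default 0.7 / 0.3,
#'   summing to 1 under the default protocol).
#' @param focalGamma focusing exponent, >= 0.
#' @param focalAlpha foreground class weight in (0, 1).
#' @param smoothEps soft-dice smoothing epsilon.
#' @return list with class `"LossConfig"`.
#' @export
lossConfig <- function(diceWeight = 0.7, focalWeight = 0.3, focalGamma = 2,
                       focalAlpha = 0.25, smoothEps = 1e-6) {
  stopifnot(diceWeight >= 0, focalWeight >= 0, focalGamma >= 0,
            focalAlpha > 0, focalAlpha < 1, smoothEps > 0)
  structure(list(diceWeight = diceWeight, focalWeight = focalWeight,
                 focalGamma = focalGamma, focalAlpha = focalAlpha,
                 smoothEps = smoothEps), class = "LossConfig")
}

#' Soft dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)`, computed over all
#' supplied pixels (per batch, flattened). Zero for a perfect binary
#' prediction (up to eps) and bounded in [0, 1].
#'
#' @param prob predicted probabilities in [0, 1] (any shape).
#' @param mask 0/1 reference of the same shape.
#' @param eps smoothing epsilon.
#' @return scalar loss.
#' @export
diceLoss <- function(prob, mask, eps = 1e-6) {
  if (length(prob) != length(mask)) stop("shape mismatch")
  1 - (2 * sum(prob * mask) + eps) / (sum(prob) + sum(mask) + eps)
}

diceLossGrad <- function(prob, mask, eps = 1e-6) {
  num <- 2 * sum(prob * mask) + eps
  den <- sum(prob) + sum(mask) + eps
  (num - 2 * mask * den) / den^2
}

#' Focal loss
#'
#' Mean over pixels of
#' `-alpha (1-p)^gamma g log p - (1-alpha) p^gamma (1-g) log(1-p)`, with
#' probabilities clamped away from 0 and 1 for stability. With gamma = 0 and
#' alpha = 0.5 this is exactly half the binary cross-entropy.
#'
#' @inheritParams diceLoss
#' @param gamma focusing exponent.
#' @param alpha foreground weight.
#' @param clamp probability clamp.
#' @return scalar loss.
#' @export
focalLoss <- function(prob, mask, gamma = 2, alpha = 0.25, clamp = 1e-7) {
  if (length(prob) != length(mask)) stop("shape mismatch")
  p <- pmin(pmax(prob, clamp), 1 - clamp)
  mean(-alpha * (1 - p)^gamma * mask * log(p) -
         (1 - alpha) * p^gamma * (1 - mask) * log(1 - p))
}

focalLossGrad <- function(prob, mask, gamma = 2, alpha = 0.25, clamp = 1e-7) {
  p <- pmin(pmax(prob, clamp), 1 - clamp)
  gFg <- if (gamma == 0) -alpha / p
         else -alpha * (-gamma * (1 - p)^(gamma - 1) * log(p) + (1 - p)^gamma / p)
  gBg <- if (gamma == 0) (1 - alpha) / (1 - p)
         else (1 - alpha) * (-gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
  (mask * gFg + (1 - mask) * gBg) / length(p)
}

#' Binary cross-entropy loss
#' @inheritParams diceLoss
#' @param clamp probability clamp.
#' @return scalar mean BCE.
#' @export
bceLoss <- function(prob, mask, clamp = 1e-7) {
  if (length(prob) != length(mask)) stop("shape mismatch")
  p <- pmin(pmax(prob, clamp), 1 - clamp)
  mean(-mask * log(p) - (1 - mask) * log(1 - p))
}

bceLossGrad <- function(prob, mask, clamp = 1e-7) {
  p <- pmin(pmax(prob, clamp), 1 - clamp)
  (-mask / p + (1 - mask) / (1 - p)) / length(p)
}

#' Compound dice + focal loss
#' @inheritParams diceLoss
#' @param cfg a [lossConfig()].
#' @return scalar `diceWeight * dice + focalWeight * focal`.
#' @export
combinedLoss <- function(prob, mask, cfg = lossConfig()) {
  cfg$diceWeight * diceLoss(prob, mask, cfg$smoothEps) +
    cfg$focalWeight * focalLoss(prob, mask, cfg$focalGamma, cfg$focalAlpha)
}

combinedLossGrad <- function(prob, mask, cfg = lossConfig()) {
  cfg$diceWeight * diceLossGrad(prob, mask, cfg$smoothEps) +
    cfg$focalWeight * focalLossGrad(prob, mask, cfg$focalGamma, cfg$focalAlpha)
}
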