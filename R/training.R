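# Training protocol: Adam at lr 1e-4 with step decay every 20 epochs, early
# stopping on the validation dice, grouped (case-level) k-fold
# cross-validation so that no case leaks between training and validation.

#' Training configuration
#'
#' Defaults follow the reference protocol: 100 epochs of Adam at learning
#' rate 1e-4 with a step-decay scheduler every 20 epochs, and early stopping
#' on a validation-dice plateau.
#'
#' @param epochs maximum epochs (>= 1).
#' @param lr initial Adam learning rate (> 0).
#' @param decayEvery epochs between step decays.
#' @param decayFactor multiplicative decay in (0, 1).
#' @param earlyStopPatience epochs without validation-dice improvement
#'   before stopping; `Inf` disables.
#' @param batchSize training batch size.
#' @param seed seed for shuffling and initialization.
#' @param kFolds folds for [crossValidate()] (>= 2).
#' @return list with class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 100L, lr = 1e-4, decayEvery = 20L,
                        decayFactor = 0.5, earlyStopPatience = 10L,
                        batchSize = 4L, seed = 1L, kFolds = 5L) {
  stopifnot(epochs >= 1, lr > 0, decayEvery >= 1, decayFactor > 0,
            decayFactor < 1, batchSize >= 1, kFolds >= 2)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 decayEvery = as.integer(decayEvery),
                 decayFactor = decayFactor,
                 earlyStopPatience = earlyStopPatience,
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 kFolds = as.integer(kFolds)), class = "TrainConfig")
}

#' Learning rate at a given epoch under the step-decay schedule
#' @param tcfg a [trainConfig()].
#' @param epoch 1-based epoch.
#' @return the (non-increasing) learning rate.
#' @export
lrAtEpoch <- function(tcfg, epoch) {
  tcfg$lr * tcfg$decayFactor^((epoch - 1) %/% tcfg$decayEvery)
}

#' Case-grouped fold assignment
#'
#' Partitions cases (not tiles) into k folds whose sizes differ by at most
#' one, deterministically for a given seed. Every tile of a case inherits
#' the case's fold, so train/validation case sets are disjoint by
#' construction: 16 cases at k = 5 give fold sizes 4, 3, 3, 3, 3.
#'
#' @param caseIds character/integer vector of case identifiers (one per
#'   tile, duplicates allowed).
#' @param k number of folds; must not exceed the number of distinct cases.
#' @param seed shuffling seed.
#' @return list with `caseFold` (named fold index per case), `folds` (list
#'   of case vectors) and `tileFold` (fold per element of `caseIds`).
#' @export
makeGroupFolds <- function(caseIds, k, seed = 1L) {
  cases <- unique(as.character(caseIds))
  if (k > length(cases))
    stop("k = ", k, " exceeds the number of cases (", length(cases), ")")
  perm <- withLocalSeed(seed, sample(cases))
  fold <- rep(seq_len(k), length.out = length(perm))
  caseFold <- setNames(fold[match(cases, perm)], cases)
  list(caseFold = caseFold,
       folds = split(names(caseFold), caseFold),
       tileFold = unname(caseFold[as.character(caseIds)]))
}

sampleToXY <- function(s) {
  x <- if (is(s$image, "ImageTile"))
    pixels(s$image) / (2^bitDepth(s$image) - 1) else s$image
  list(x = x, y = matrix(as.numeric(s$mask), nrow(s$mask), ncol(s$mask)))
}

stackBatch <- function(xy) {
  H <- nrow(xy[[1]]$x); W <- ncol(xy[[1]]$x)
  n <- length(xy)
  x <- array(0, c(H, W, 1, n)); y <- array(0, c(H, W, 1, n))
  for (i in seq_len(n)) { x[, , 1, i] <- xy[[i]]$x; y[, , 1, i] <- xy[[i]]$y }
  list(x = x, y = y)
}

hardDice <- function(prob, mask, threshold = 0.5) {
  p <- prob > threshold; g <- mask > 0
  tp <- sum(p & g)
  den <- 2 * tp + sum(p & !g) + sum(!p & g)
  if (den == 0) 1 else 2 * tp / den
}

valDice <- function(model, valSet, threshold = 0.5) {
  mean(vapply(valSet, function(s) {
    xy <- sampleToXY(s)
    hardDice(predictProb(model, xy$x), xy$y, threshold)
  }, numeric(1)))
}

#' Train a segmentation model
#'
#' Runs seeded mini-batch Adam with the step-decay schedule, evaluating the
#' hard dice on the validation set after every epoch, retaining the
#' best-validation parameters and stopping early after
#' `earlyStopPatience` epochs without improvement. DCAU-Net trains with the
#' compound dice+focal loss; pass `loss = "bce"` for the U-Net baseline
#' protocol.
#'
#' @param model a model handle from [buildDcauNet()] or
#'   [buildUnetBaseline()].
#' @param trainSet,valSet lists of samples, each `list(image, mask)` where
#'   `image` is an [ImageTile-class] or a [0,1] matrix; train and
#'   validation must not share cases.
#' @param tcfg a [trainConfig()].
#' @param lcfg a [lossConfig()].
#' @param loss `"combined"` or `"bce"`.
#' @param verbose print one line per epoch to stderr.
#' @return list with `model` (best-validation parameters, marked trained)
#'   and `history` (data.frame: epoch, lr, train_loss, val_dice).
#' @export
trainModel <- function(model, trainSet, valSet, tcfg = trainConfig(),
                       lcfg = lossConfig(), loss = c("combined", "bce"),
                       verbose = FALSE) {
  loss <- match.arg(loss)
  if (!length(trainSet)) stop("empty training set")
  if (!length(valSet)) stop("empty validation set")
  lossFn <- function(prob, y) switch(loss,
    combined = combinedLoss(prob, y, lcfg), bce = bceLoss(prob, y))
  gradFn <- function(prob, y) switch(loss,
    combined = combinedLossGrad(prob, y, lcfg), bce = bceLossGrad(prob, y))
  withLocalSeed(tcfg$seed, {
    state <- list()
    t <- 0L
    best <- list(dice = -Inf, params = model$params, epoch = 0L)
    bad <- 0L
    hist <- data.frame(epoch = integer(0), lr = numeric(0),
                       train_loss = numeric(0), val_dice = numeric(0))
    for (ep in seq_len(tcfg$epochs)) {
      lr <- lrAtEpoch(tcfg, ep)
      ord <- sample(length(trainSet))
      losses <- numeric(0)
      for (i in seq(1, length(ord), by = tcfg$batchSize)) {
        idx <- ord[i:min(i + tcfg$batchSize - 1L, length(ord))]
        b <- stackBatch(lapply(trainSet[idx], sampleToXY))
        fw <- modelFwd(model, b$x, train = TRUE)
        model <- fw$model
        l <- lossFn(fw$prob, b$y)
        if (!is.finite(l))
          stop("non-finite loss at epoch ", ep, "; aborting training")
        losses <- c(losses, l)
        g <- modelBwd(model, fw, gradFn(fw$prob, b$y))
        t <- t + 1L
        up <- adamStep(model$params, g, state, lr, t)
        model$params <- up$p
        state <- up$s
      }
      vd <- valDice(model, valSet)
      hist[nrow(hist) + 1L, ] <- list(ep, lr, mean(losses), vd)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2g  loss %.4f  val dice %.4f",
                        ep, lr, mean(losses), vd))
      if (vd > best$dice + 1e-6) {
        best <- list(dice = vd, params = model$params, epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > tcfg$earlyStopPatience) break
      }
    }
    model$params <- best$params
    model$trained <- TRUE
    model$bestValDice <- best$dice
    list(model = model, history = hist)
  })
}

#' Grouped k-fold cross-validation
#'
#' Trains one model per fold, each fold serving once as validation, and
#' reports the per-fold best validation dice with mean and sample sd.
#'
#' @param dataset list of samples `list(image, mask, case)`.
#' @param tcfg a [trainConfig()] (supplies `kFolds` and the seed).
#' @param lcfg a [lossConfig()].
#' @param builder zero-argument function returning a fresh model handle.
#' @param loss forwarded to [trainModel()].
#' @param keepModels retain the trained models (memory permitting).
#' @return list with `perFold` (data.frame fold/n_val/dice), `mean`, `sd`,
#'   `folds` (the [makeGroupFolds()] assignment) and optionally `models`.
#' @export
crossValidate <- function(dataset, tcfg = trainConfig(), lcfg = lossConfig(),
                          builder = function() buildDcauNet(),
                          loss = "combined", keepModels = FALSE) {
  cases <- vapply(dataset, function(s) as.character(s$case), character(1))
  fa <- makeGroupFolds(cases, tcfg$kFolds, tcfg$seed)
  dice <- numeric(tcfg$kFolds)
  nval <- integer(tcfg$kFolds)
  models <- if (keepModels) vector("list", tcfg$kFolds) else NULL
  for (f in seq_len(tcfg$kFolds)) {
    vi <- fa$tileFold == f
    fit <- trainModel(builder(), dataset[!vi], dataset[vi], tcfg, lcfg,
                      loss = loss)
    dice[f] <- fit$model$bestValDice
    nval[f] <- sum(vi)
    if (keepModels) models[[f]] <- fit$model
  }
  out <- list(perFold = data.frame(fold = seq_len(tcfg$kFolds), n_val = nval,
                                   dice = dice),
              mean = mean(dice), sd = sd(dice), folds = fa)
  if (keepModels) out$models <- models
  out
}
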