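test_that("the step-decay schedule is the documented staircase", {
  tc <- trainConfig()
  expect_equal(tc$lr, 1e-4)
  expect_equal(lrAtEpoch(tc, 1), 1e-4)
  expect_equal(lrAtEpoch(tc, 20), 1e-4)
  expect_equal(lrAtEpoch(tc, 21), 1e-4 * 0.5)
  expect_equal(lrAtEpoch(tc, 41), 1e-4 * 0.25)
  lrs <- vapply(1:100, function(e) lrAtEpoch(tc, e), numeric(1))
  expect_true(all(diff(lrs) <= 0))
})

test_that("grouped folds partition cases evenly with no leakage", {
  tiles <- rep(sprintf("rabbit%02d", 1:16), each = 3)
  fa <- makeGroupFolds(tiles, 5, seed = 1)
  sizes <- sort(vapply(fa$folds, length, integer(1)), decreasing = TRUE)
  expect_identical(unname(sizes), c(4L, 3L, 3L, 3L, 3L))
  # every tile's fold equals its case's fold
  expect_identical(fa$tileFold, unname(fa$caseFold[tiles]))
  # folds partition the cases
  expect_setequal(unlist(fa$folds), unique(tiles))
  # deterministic under the seed, different under another
  expect_identical(fa$caseFold, makeGroupFolds(tiles, 5, seed = 1)$caseFold)
  expect_false(identical(fa$caseFold,
                         makeGroupFolds(tiles, 5, seed = 2)$caseFold))
  # leave-one-case-out and error case
  loo <- makeGroupFolds(unique(tiles), 16, seed = 1)
  expect_identical(unname(vapply(loo$folds, length, integer(1))),
                   rep(1L, 16))
  expect_error(makeGroupFolds(tiles, 17, seed = 1), "exceeds")
})

test_that("training improves held-out dice and honours early stopping", {
  trainSet <- lapply(1:8, function(i) tinySample(200 + i, (i - 1) %/% 4 + 1))
  valSet <- lapply(1:2, function(i) tinySample(300 + i, 9))
  m <- buildDcauNet(modelConfig(depth = 2, baseChannels = 6), seed = 1)
  d0 <- gobletseg:::valDice(m, valSet)
  fit <- trainModel(m, trainSet, valSet,
                    trainConfig(epochs = 4, lr = 6e-3, batchSize = 4,
                                seed = 5),
                    lossConfig())
  expect_identical(nrow(fit$history), 4L)
  expect_true(all(c("epoch", "lr", "train_loss", "val_dice") %in%
                    names(fit$history)))
  expect_gt(fit$model$bestValDice, d0)
  expect_true(fit$model$trained)
  # patience 0: stops at the first non-improving epoch
  fit0 <- trainModel(buildDcauNet(modelConfig(depth = 2, baseChannels = 4),
                                  seed = 2),
                     trainSet[1:4], valSet,
                     trainConfig(epochs = 30, lr = 1e-5, batchSize = 4,
                                 seed = 6, earlyStopPatience = 0),
                     lossConfig())
  expect_lt(nrow(fit0$history), 30L)
  expect_error(trainModel(m, list(), valSet), "empty")
})

test_that("training is reproducible under a fixed seed", {
  trainSet <- lapply(1:4, function(i) tinySample(210 + i, i))
  valSet <- list(tinySample(310, 9))
  tc <- trainConfig(epochs = 2, lr = 3e-3, batchSize = 2, seed = 11)
  f1 <- trainModel(buildDcauNet(modelConfig(depth = 2, baseChannels = 4),
                                seed = 3), trainSet, valSet, tc)
  f2 <- trainModel(buildDcauNet(modelConfig(depth = 2, baseChannels = 4),
                                seed = 3), trainSet, valSet, tc)
  expect_identical(f1$history, f2$history)
})

test_that("cross-validation runs each fold once as validation", {
  dataset <- lapply(1:9, function(i) tinySample(220 + i, (i - 1) %/% 3 + 1,
                                                size = 32L))
  cv <- crossValidate(dataset,
                      trainConfig(epochs = 1, lr = 3e-3, batchSize = 4,
                                  seed = 7, kFolds = 3),
                      lossConfig(),
                      builder = function()
                        buildDcauNet(modelConfig(depth = 1,
                                                 baseChannels = 4), seed = 8))
  expect_identical(nrow(cv$perFold), 3L)
  expect_length(cv$perFold$dice, 3)
  # every sample is validated exactly once across folds
  expect_identical(sum(cv$perFold$n_val), 9L)
  expect_identical(sort(unique(cv$folds$tileFold)), 1:3)
  expect_equal(cv$mean, mean(cv$perFold$dice))
})

test_that("baseline U-Net trains under the identical loop with BCE", {
  trainSet <- lapply(1:4, function(i) tinySample(230 + i, i, size = 32L))
  valSet <- list(tinySample(320, 9, size = 32L))
  fit <- trainModel(buildUnetBaseline(modelConfig(depth = 1,
                                                  baseChannels = 4,
                                                  useResidual = FALSE),
                                      seed = 4),
                    trainSet, valSet,
                    trainConfig(epochs = 2, lr = 3e-3, batchSize = 2,
                                seed = 9),
                    loss = "bce")
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$train_loss)))
})
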