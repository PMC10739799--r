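test_that("GCA matches the scalar-loop squeeze oracle and analytic cases", {
  set.seed(31)
  for (rep in 1:5) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:8, 1))
    sem <- array(rnorm(prod(d)), d)
    tex <- array(rnorm(prod(d)), d)
    g <- gca(sem, tex, weights = rnorm(d[3]), bias = rnorm(1))
    # channel descriptor = per-channel spatial mean of the fused map
    expect_equal(g$descriptor, loopChannelMean(sem + tex), tolerance = 1e-6)
    # attention strictly inside (0, 1); output finite
    expect_true(all(g$attention > 0 & g$attention < 1))
    expect_true(all(is.finite(g$output)))
  }
  # zero 1x1-conv weights: attention = 0.5 everywhere, so the refined map
  # is 0.5 x per-channel mean, broadcast over space
  sem <- array(runif(4 * 6 * 3), c(4, 6, 3))
  tex <- array(runif(4 * 6 * 3), c(4, 6, 3))
  g0 <- gca(sem, tex)
  expect_equal(unique(as.vector(g0$attention)), 0.5)
  fused <- sem + tex
  ms <- loopChannelMean(fused)
  for (c in 1:3)
    expect_equal(g0$output[, , c], 0.5 * ms[c] * fused[, , c],
                 tolerance = 1e-12)
  # constant input per channel: descriptor recovers the constants exactly
  cst <- array(rep(c(2, -1, 0.5), each = 20), c(4, 5, 3))
  gc2 <- gca(cst, cst * 0)
  expect_equal(gc2$descriptor, c(2, -1, 0.5))
  expect_error(gca(sem, tex[, 1:3, , drop = FALSE]), "differ")
})

test_that("semantic and texture channels honour their shape contracts", {
  cfg <- modelConfig(depth = 1, baseChannels = 6, textureKernelLen = 7)
  st <- dccStage(1, 6, cfg, seed = 2)
  x <- array(runif(16 * 16), c(16, 16, 1))
  sem <- semanticChannel(x, st)
  tex <- textureChannel(x, st)
  expect_identical(dim(sem), c(16L, 16L, 6L))
  expect_identical(dim(tex), dim(sem))
  # factorized kx1 + 1xk pair is cheaper than a full kxk kernel
  k <- 7; cin <- 4; cout <- 8
  expect_lt(2 * k * cin * cout, k^2 * cin * cout)
  expect_equal(length(dccStage(cin, cout, cfg, seed = 1)$texA$w),
               k * 1 * cin * cout)
})

test_that("receptive fields grow as designed (forward support probes)", {
  cfg <- modelConfig(depth = 1, baseChannels = 4, textureKernelLen = 7,
                     useResidual = FALSE)
  st <- dccStage(1, 4, cfg, seed = 3)
  probe <- function(fn) {
    x0 <- array(0.5, c(15, 15, 1))
    y0 <- fn(x0)
    x1 <- x0; x1[8, 8, 1] <- 5
    y1 <- fn(x1)
    delta <- apply(abs(y1 - y0), c(1, 2), max)
    which(delta > 1e-10, arr.ind = TRUE)
  }
  supSingle <- probe(function(x) semanticChannel(x, st, path = "single"))
  supStacked <- probe(function(x) semanticChannel(x, st, path = "stacked"))
  supTex <- probe(function(x) textureChannel(x, st))
  spread <- function(s) c(diff(range(s[, 1])), diff(range(s[, 2]))) + 1
  expect_identical(spread(supSingle), c(3, 3))    # one 3x3 conv
  expect_identical(spread(supStacked), c(5, 5))   # two stacked 3x3 convs
  expect_identical(spread(supTex), c(7, 7))       # 7x1 then 1x7
})

test_that("both networks map inputs to same-size sigmoid probability maps", {
  cfg <- modelConfig(depth = 2, baseChannels = 4)
  md <- buildDcauNet(cfg, seed = 1)
  mu <- buildUnetBaseline(modelConfig(depth = 2, baseChannels = 4,
                                      useResidual = FALSE), seed = 1)
  x <- matrix(runif(64 * 64), 64)
  for (m in list(md, mu)) {
    p <- predictProb(m, x)
    expect_identical(dim(p), c(64L, 64L))
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(sd(p), 0)
  }
  # identical batches accepted by both (interface parity)
  xb <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  fd <- gobletseg:::modelFwd(md, xb)
  fu <- gobletseg:::modelFwd(mu, xb)
  expect_identical(dim(fd$prob), dim(fu$prob))
  expect_error(predictProb(md, matrix(runif(30 * 30), 30)), "divisible")
})

test_that("spatial dims halve per encoder stage", {
  cfg <- modelConfig(depth = 3, baseChannels = 2)
  m <- buildDcauNet(cfg, seed = 4)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw <- gobletseg:::modelFwd(m, x)
  for (s in 1:3)
    expect_equal(fw$caches$pools[[s]]$xdim[1], 32 / 2^(s - 1))
  expect_identical(dim(fw$prob)[1:2], c(32L, 32L))
})

test_that("gradients are finite and match finite differences", {
  set.seed(5)
  cfg <- modelConfig(depth = 2, baseChannels = 4, textureKernelLen = 5)
  m <- buildDcauNet(cfg, seed = 6)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  lc <- lossConfig()
  fw <- gobletseg:::modelFwd(m, x, train = TRUE)
  g <- gobletseg:::modelBwd(m, fw, gobletseg:::combinedLossGrad(fw$prob, y, lc))
  walk <- function(t) {
    if (is.list(t)) return(all(vapply(t, walk, logical(1))))
    all(is.finite(t))
  }
  expect_true(walk(g))
  lossAt <- function(params) {
    mm <- m; mm$params <- params
    combinedLoss(gobletseg:::modelFwd(mm, x, train = TRUE)$prob, y, lc)
  }
  paths <- list(list("stages", 1, "semA", "w"),
                list("stages", 2, "gca", "w"),
                list("dec", 2, "upc", "w"),
                list("bottleneck", "b1", "gamma"),
                list("final", "b"))
  eps <- 1e-5
  for (path in paths) {
    leaf <- getLeaf(m$params, path)
    i <- sample(length(leaf), 1)
    up <- leaf; up[i] <- up[i] + eps
    dn <- leaf; dn[i] <- dn[i] - eps
    num <- (lossAt(setLeaf(m$params, path, up)) -
              lossAt(setLeaf(m$params, path, dn))) / (2 * eps)
    ana <- getLeaf(g, path)[i]
    # mixed absolute/relative bound: finite differences carry O(eps) noise
    expect_lt(abs(ana - num), 1e-6 + 1e-2 * abs(num))
  }
})

test_that("baseline at classic widths counts ~31M parameters", {
  m <- buildUnetBaseline(modelConfig(depth = 4, baseChannels = 64,
                                     useResidual = FALSE), seed = 1)
  # closed-form count of the classic contracting/expanding layout
  w <- c(64, 128, 256, 512)
  cin <- c(1, w[-4])
  enc <- sum(9 * (cin * w + w * w) + 2 * w)            # conv weights + biases
  bn <- sum(2 * 2 * w)                                 # gamma + beta per block
  bot <- 9 * (512 * 1024 + 1024 * 1024) + 1024 + 1024 + 2 * 2 * 1024
  dec <- 0
  for (s in 4:1) {
    cup <- if (s == 4) 1024 else w[s + 1]
    dec <- dec + 4 * cup * w[s] + w[s] +               # 2x2 channel-halving
      9 * (2 * w[s] * w[s] + w[s] * w[s]) + 2 * w[s] + # two 3x3 blocks
      2 * 3 * w[s]                                     # their BN params
  }
  closed <- enc + bn + bot + dec + 64 + 1              # + 1x1 sigmoid head
  expect_identical(nParams(m), closed)
  expect_equal(nParams(m) / 1e6, 31, tolerance = 0.01)
})

test_that("zero input stays zero through an eval-mode block", {
  # He init draws weights ~ N(0, .); biases, BN shifts start at zero and
  # running stats at (0, 1), so a zero input maps to zero after conv+BN+ReLU
  p <- gobletseg:::blockInit(3, 3, 2, 3, residual = FALSE)
  x <- array(0, c(8, 8, 2, 1))
  y <- gobletseg:::blockFwd(p, x, train = FALSE)$y
  expect_true(all(y == 0))
})

test_that("models round-trip through checkpoints", {
  m <- buildDcauNet(modelConfig(depth = 1, baseChannels = 2), seed = 9)
  d <- withr::local_tempdir()
  ck <- file.path(d, "m.rds")
  saveModel(m, ck)
  expect_true(file.exists(file.path(d, "m.yaml")))
  m2 <- loadModel(ck)
  x <- matrix(runif(16 * 16), 16)
  expect_identical(predictProb(m, x), predictProb(m2, x))
})
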