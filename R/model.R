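# DCAU-Net and the standard U-Net baseline. Both are encoder-decoder
# networks ending in a one-channel sigmoid probability map of the input
# size. The DCAU-Net encoder stage is a dual-channel convolution (DCC):
# a semantic channel (a single 3x3 block in parallel with two stacked 3x3
# blocks, summed) plus a texture channel (asymmetric kx1 then 1xk blocks),
# fused element-wise; the fused map feeds both a 2x2 max-pool (down the
# encoder) and a global channel attention (GCA) module whose output is the
# skip connection into the mirrored decoder.

#' Model configuration
#'
#' @param depth number of encoder stages (each halves the spatial dims).
#' @param baseChannels channels of the first stage; doubled per stage.
#' @param textureKernelLen odd length k (>= 3) of the asymmetric kx1 / 1xk
#'   texture kernels.
#' @param useResidual identity/projection shortcut over each conv block.
#' @param inChannels input image channels.
#' @return list with class `"ModelConfig"`.
#' @export
modelConfig <- function(depth = 4L, baseChannels = 64L, textureKernelLen = 7L,
                        useResidual = TRUE, inChannels = 1L) {
  stopifnot(depth >= 1, baseChannels >= 1,
            textureKernelLen >= 3, textureKernelLen %% 2 == 1)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 textureKernelLen = as.integer(textureKernelLen),
                 useResidual = isTRUE(useResidual),
                 inChannels = as.integer(inChannels)),
            class = "ModelConfig")
}

stageWidth <- function(config, s) config$baseChannels * 2L^(s - 1L)

#' Initialize the parameters of one dual-channel convolution stage
#'
#' @param cin input channels of the stage.
#' @param width output channels (stage width).
#' @param config a [modelConfig()] (supplies the texture kernel length and
#'   residual flag).
#' @param seed optional seed for reproducible He-normal initialization.
#' @return nested parameter list (semantic blocks, texture blocks, GCA).
#' @export
dccStage <- function(cin, width, config = modelConfig(), seed = NULL) {
  init <- function() {
    k <- config$textureKernelLen
    r <- config$useResidual
    list(semA = blockInit(3, 3, cin, width, r),
         semB1 = blockInit(3, 3, cin, width, r),
         semB2 = blockInit(3, 3, width, width, r),
         texA = blockInit(k, 1, cin, width, r),
         texB = blockInit(1, k, width, width, r),
         gca = gcaInit(width))
  }
  if (is.null(seed)) init() else withLocalSeed(seed, init())
}

dccStageFwd <- function(st, x, train) {
  a <- blockFwd(st$semA, x, train); st$semA <- a$p
  b1 <- blockFwd(st$semB1, x, train); st$semB1 <- b1$p
  b2 <- blockFwd(st$semB2, b1$y, train); st$semB2 <- b2$p
  sem <- a$y + b2$y
  t1 <- blockFwd(st$texA, x, train); st$texA <- t1$p
  t2 <- blockFwd(st$texB, t1$y, train); st$texB <- t2$p
  fused <- sem + t2$y
  g <- gcaFwd(st$gca, fused)
  list(fused = fused, skip = g$y, st = st,
       cache = list(a = a$cache, b1 = b1$cache, b2 = b2$cache,
                    t1 = t1$cache, t2 = t2$cache, gca = g$cache))
}

# dskip: gradient flowing into the GCA output; dfused: gradient flowing
# into the fused map from the pooling path.
dccStageBwd <- function(st, cache, dfused, dskip) {
  g <- list()
  gb <- gcaBwd(st$gca, cache$gca, dskip)
  g$gca <- gb$grads
  dfused <- dfused + gb$dfused
  t2 <- blockBwd(st$texB, cache$t2, dfused); g$texB <- t2$grads
  t1 <- blockBwd(st$texA, cache$t1, t2$dx); g$texA <- t1$grads
  b2 <- blockBwd(st$semB2, cache$b2, dfused); g$semB2 <- b2$grads
  b1 <- blockBwd(st$semB1, cache$b1, b2$dx); g$semB1 <- b1$grads
  a <- blockBwd(st$semA, cache$a, dfused); g$semA <- a$grads
  list(dx = a$dx + b1$dx + t1$dx, grads = g)
}

#' Build a DCAU-Net model
#'
#' Encoder: `depth` DCC stages, each followed by 2x2 max-pooling of the
#' fused map, with the stage's GCA output as the skip connection. A
#' two-block bottleneck at double the deepest width. Decoder: bilinear
#' upsampling + a 3x3 block per stage, concatenated with the GCA skip and
#' refined by two 3x3 blocks. Head: 1x1 convolution + sigmoid.
#'
#' @param config a [modelConfig()].
#' @param seed optional initialization seed.
#' @return a model handle (list with class `"gcSegModel"`).
#' @export
buildDcauNet <- function(config = modelConfig(), seed = NULL) {
  build <- function() {
    d <- config$depth
    stages <- vector("list", d)
    cin <- config$inChannels
    for (s in seq_len(d)) {
      w <- stageWidth(config, s)
      stages[[s]] <- dccStage(cin, w, config)
      cin <- w
    }
    wd <- stageWidth(config, d)
    r <- config$useResidual
    dec <- vector("list", d)
    for (s in d:1) {
      w <- stageWidth(config, s)
      cup <- if (s == d) 2L * wd else stageWidth(config, s + 1L)
      dec[[s]] <- list(upc = blockInit(3, 3, cup, w, r),
                       d1 = blockInit(3, 3, 2L * w, w, r),
                       d2 = blockInit(3, 3, w, w, r))
    }
    params <- list(stages = stages,
                   bottleneck = list(b1 = blockInit(3, 3, wd, 2L * wd, r),
                                     b2 = blockInit(3, 3, 2L * wd, 2L * wd, r)),
                   dec = dec,
                   final = convInit(1, 1, config$baseChannels, 1))
    # bias the sigmoid head toward the background prior (focal-loss
    # convention): rare-foreground tasks start near the base rate instead
    # of at p = 0.5, which removes the early plateau
    params$final$b[] <- -2
    structure(list(arch = "dcau", config = config, params = params),
              class = "gcSegModel")
  }
  if (is.null(seed)) build() else withLocalSeed(seed, build())
}

#' Build the standard U-Net baseline
#'
#' The classic contracting/expanding architecture: two 3x3 conv blocks per
#' stage, 2x2 max-pooling, a two-block bottleneck, and a decoder of
#' bilinear upsampling + 2x2 channel-halving convolution, skip
#' concatenation and two 3x3 blocks, ending in a 1x1 sigmoid head. At the
#' classic widths (depth 4, 64 base channels) the trainable parameter count
#' is ~31M. Accepts the same batches and returns the same probability-map
#' contract as [buildDcauNet()].
#'
#' @inheritParams buildDcauNet
#' @return a model handle (list with class `"gcSegModel"`).
#' @export
buildUnetBaseline <- function(config = modelConfig(useResidual = FALSE),
                              seed = NULL) {
  build <- function() {
    d <- config$depth
    stages <- vector("list", d)
    cin <- config$inChannels
    for (s in seq_len(d)) {
      w <- stageWidth(config, s)
      stages[[s]] <- list(e1 = blockInit(3, 3, cin, w, FALSE),
                          e2 = blockInit(3, 3, w, w, FALSE))
      cin <- w
    }
    wd <- stageWidth(config, d)
    dec <- vector("list", d)
    for (s in d:1) {
      w <- stageWidth(config, s)
      cup <- if (s == d) 2L * wd else stageWidth(config, s + 1L)
      dec[[s]] <- list(upc = blockInit(2, 2, cup, w, FALSE),
                       d1 = blockInit(3, 3, 2L * w, w, FALSE),
                       d2 = blockInit(3, 3, w, w, FALSE))
    }
    params <- list(stages = stages,
                   bottleneck = list(b1 = blockInit(3, 3, wd, 2L * wd, FALSE),
                                     b2 = blockInit(3, 3, 2L * wd, 2L * wd, FALSE)),
                   dec = dec,
                   final = convInit(1, 1, config$baseChannels, 1))
    # bias the sigmoid head toward the background prior (focal-loss
    # convention): rare-foreground tasks start near the base rate instead
    # of at p = 0.5, which removes the early plateau
    params$final$b[] <- -2
    structure(list(arch = "unet", config = config, params = params),
              class = "gcSegModel")
  }
  if (is.null(seed)) build() else withLocalSeed(seed, build())
}

#' @export
print.gcSegModel <- function(x, ...) {
  cat(sprintf("<%s> depth %d, base %d channels, %s parameters\n",
              if (x$arch == "dcau") "DCAU-Net" else "U-Net baseline",
              x$config$depth, x$config$baseChannels,
              format(nParams(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a model handle.
#' @return integer count (running batch-norm statistics excluded).
#' @export
nParams <- function(model) {
  count <- function(p, nm = "") {
    if (is.list(p)) {
      nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
      return(sum(vapply(seq_along(p),
                        function(i) count(p[[i]], nms[i]), numeric(1))))
    }
    if (nm %in% c("rm", "rv", "residual")) 0 else length(p)
  }
  count(model$params)
}

checkInputDims <- function(model, H, W) {
  f <- 2L^model$config$depth
  if (H %% f != 0L || W %% f != 0L)
    stop("input ", H, " x ", W, " is not divisible by 2^depth = ", f,
         "; pad or crop the tile")
}

modelFwd <- function(model, x, train = FALSE) {
  x <- asBatch(x)
  d <- dim(x)
  checkInputDims(model, d[1], d[2])
  if (model$arch == "dcau") dcauFwd(model, x, train) else unetFwd(model, x, train)
}

modelBwd <- function(model, fw, dprob) {
  dlogit <- dprob * fw$prob * (1 - fw$prob)
  dim(dlogit) <- dim(fw$prob)
  if (model$arch == "dcau") dcauBwd(model, fw, dlogit)
  else unetBwd(model, fw, dlogit)
}

dcauFwd <- function(model, x, train) {
  p <- model$params
  d <- model$config$depth
  caches <- list(stages = vector("list", d), pools = vector("list", d),
                 dec = vector("list", d))
  skips <- vector("list", d)
  inp <- x
  for (s in seq_len(d)) {
    sf <- dccStageFwd(p$stages[[s]], inp, train)
    p$stages[[s]] <- sf$st
    caches$stages[[s]] <- sf$cache
    skips[[s]] <- sf$skip
    pool <- nn_maxpool_fwd(sf$fused)
    caches$pools[[s]] <- list(idx = pool$idx, xdim = dim(sf$fused))
    inp <- pool$y
  }
  b1 <- blockFwd(p$bottleneck$b1, inp, train); p$bottleneck$b1 <- b1$p
  b2 <- blockFwd(p$bottleneck$b2, b1$y, train); p$bottleneck$b2 <- b2$p
  caches$bottleneck <- list(b1 = b1$cache, b2 = b2$cache)
  y <- b2$y
  for (s in d:1) {
    up <- nn_upsample2_fwd(y)
    u <- blockFwd(p$dec[[s]]$upc, up, train); p$dec[[s]]$upc <- u$p
    cat2 <- ccat(skips[[s]], u$y)
    d1 <- blockFwd(p$dec[[s]]$d1, cat2, train); p$dec[[s]]$d1 <- d1$p
    d2 <- blockFwd(p$dec[[s]]$d2, d1$y, train); p$dec[[s]]$d2 <- d2$p
    caches$dec[[s]] <- list(u = u$cache, d1 = d1$cache, d2 = d2$cache,
                            skipC = dim(skips[[s]])[3])
    y <- d2$y
  }
  logits <- nn_conv_fwd(y, p$final$w, p$final$b)
  prob <- 1 / (1 + exp(-logits))
  model$params <- p
  list(prob = prob, caches = caches, model = model, head = y)
}

dcauBwd <- function(model, fw, dlogit) {
  p <- model$params
  caches <- fw$caches
  d <- model$config$depth
  g <- list(stages = vector("list", d), dec = vector("list", d))
  fr <- nn_conv_bwd(fw$head, p$final$w, dlogit)
  g$final <- list(w = fr$dw, b = fr$db)
  dy <- fr$dx
  dskips <- vector("list", d)
  for (s in seq_len(d)) {
    dc <- caches$dec[[s]]
    d2 <- blockBwd(p$dec[[s]]$d2, dc$d2, dy)
    d1 <- blockBwd(p$dec[[s]]$d1, dc$d1, d2$dx)
    sp <- csplit(d1$dx, dc$skipC)
    dskips[[s]] <- sp[[1]]
    u <- blockBwd(p$dec[[s]]$upc, dc$u, sp[[2]])
    dy <- nn_upsample2_bwd(u$dx)
    g$dec[[s]] <- list(upc = u$grads, d1 = d1$grads, d2 = d2$grads)
  }
  b2 <- blockBwd(p$bottleneck$b2, caches$bottleneck$b2, dy)
  b1 <- blockBwd(p$bottleneck$b1, caches$bottleneck$b1, b2$dx)
  g$bottleneck <- list(b1 = b1$grads, b2 = b2$grads)
  dpool <- b1$dx
  for (s in d:1) {
    pl <- caches$pools[[s]]
    dfused <- nn_maxpool_bwd(pl$idx, dpool, pl$xdim)
    sb <- dccStageBwd(p$stages[[s]], caches$stages[[s]], dfused, dskips[[s]])
    g$stages[[s]] <- sb$grads
    dpool <- sb$dx
  }
  g
}

unetFwd <- function(model, x, train) {
  p <- model$params
  d <- model$config$depth
  caches <- list(stages = vector("list", d), pools = vector("list", d),
                 dec = vector("list", d))
  skips <- vector("list", d)
  inp <- x
  for (s in seq_len(d)) {
    e1 <- blockFwd(p$stages[[s]]$e1, inp, train); p$stages[[s]]$e1 <- e1$p
    e2 <- blockFwd(p$stages[[s]]$e2, e1$y, train); p$stages[[s]]$e2 <- e2$p
    caches$stages[[s]] <- list(e1 = e1$cache, e2 = e2$cache)
    skips[[s]] <- e2$y
    pool <- nn_maxpool_fwd(e2$y)
    caches$pools[[s]] <- list(idx = pool$idx, xdim = dim(e2$y))
    inp <- pool$y
  }
  b1 <- blockFwd(p$bottleneck$b1, inp, train); p$bottleneck$b1 <- b1$p
  b2 <- blockFwd(p$bottleneck$b2, b1$y, train); p$bottleneck$b2 <- b2$p
  caches$bottleneck <- list(b1 = b1$cache, b2 = b2$cache)
  y <- b2$y
  for (s in d:1) {
    up <- nn_upsample2_fwd(y)
    u <- blockFwd(p$dec[[s]]$upc, up, train); p$dec[[s]]$upc <- u$p
    cat2 <- ccat(skips[[s]], u$y)
    d1 <- blockFwd(p$dec[[s]]$d1, cat2, train); p$dec[[s]]$d1 <- d1$p
    d2 <- blockFwd(p$dec[[s]]$d2, d1$y, train); p$dec[[s]]$d2 <- d2$p
    caches$dec[[s]] <- list(u = u$cache, d1 = d1$cache, d2 = d2$cache,
                            skipC = dim(skips[[s]])[3])
    y <- d2$y
  }
  logits <- nn_conv_fwd(y, p$final$w, p$final$b)
  prob <- 1 / (1 + exp(-logits))
  model$params <- p
  list(prob = prob, caches = caches, model = model, head = y)
}

unetBwd <- function(model, fw, dlogit) {
  p <- model$params
  caches <- fw$caches
  d <- model$config$depth
  g <- list(stages = vector("list", d), dec = vector("list", d))
  fr <- nn_conv_bwd(fw$head, p$final$w, dlogit)
  g$final <- list(w = fr$dw, b = fr$db)
  dy <- fr$dx
  dskips <- vector("list", d)
  for (s in seq_len(d)) {
    dc <- caches$dec[[s]]
    d2 <- blockBwd(p$dec[[s]]$d2, dc$d2, dy)
    d1 <- blockBwd(p$dec[[s]]$d1, dc$d1, d2$dx)
    sp <- csplit(d1$dx, dc$skipC)
    dskips[[s]] <- sp[[1]]
    u <- blockBwd(p$dec[[s]]$upc, dc$u, sp[[2]])
    dy <- nn_upsample2_bwd(u$dx)
    g$dec[[s]] <- list(upc = u$grads, d1 = d1$grads, d2 = d2$grads)
  }
  b2 <- blockBwd(p$bottleneck$b2, caches$bottleneck$b2, dy)
  b1 <- blockBwd(p$bottleneck$b1, caches$bottleneck$b1, b2$dx)
  g$bottleneck <- list(b1 = b1$grads, b2 = b2$grads)
  dpool <- b1$dx
  for (s in d:1) {
    pl <- caches$pools[[s]]
    de2 <- nn_maxpool_bwd(pl$idx, dpool, pl$xdim) + dskips[[s]]
    e2 <- blockBwd(p$stages[[s]]$e2, caches$stages[[s]]$e2, de2)
    e1 <- blockBwd(p$stages[[s]]$e1, caches$stages[[s]]$e1, e2$dx)
    g$stages[[s]] <- list(e1 = e1$grads, e2 = e2$grads)
    dpool <- e1$dx
  }
  g
}

#' Predict per-pixel foreground probabilities
#'
#' Runs the model in evaluation mode (batch norm uses running statistics).
#' Input spatial dims must be divisible by `2^depth`.
#'
#' @param model a trained model handle.
#' @param tiles an [ImageTile-class], a numeric matrix on the native
#'   intensity scale, a matrix already in [0, 1], or a list of these.
#' @return a probability matrix in [0, 1], or a list of them.
#' @export
predictProb <- function(model, tiles) {
  one <- function(t) {
    x <- if (is(t, "ImageTile")) pixels(t) / (2^bitDepth(t) - 1) else t
    if (max(x) > 1) stop("matrix input must be normalized to [0, 1]")
    fw <- modelFwd(model, asBatch(x), train = FALSE)
    matrix(fw$prob, nrow(x), ncol(x))
  }
  if (is.list(tiles) && !is(tiles, "ImageTile")) lapply(tiles, one)
  else one(tiles)
}

#' Save / load a model
#'
#' The checkpoint is the R-native serialization of the parameter tree plus a
#' YAML sidecar describing the architecture.
#'
#' @param model a model handle.
#' @param path checkpoint path (`.rds`); the sidecar gets extension `.yaml`.
#' @return `saveModel` the paths, invisibly; `loadModel` the model handle.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  side <- paste0(tools::file_path_sans_ext(path), ".yaml")
  yaml::write_yaml(c(list(arch = model$arch,
                          nParams = nParams(model)),
                     unclass(model$config)), side)
  invisible(c(checkpoint = path, arch = side))
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

# ---- standalone operation surfaces (single 3-d feature maps) --------------

#' Semantic channel of a DCC stage
#'
#' Runs the multi-scale semantic channel -- a single 3x3 conv block in
#' parallel with two stacked 3x3 conv blocks (each conv + BN + ReLU with a
#' residual shortcut), summed -- in evaluation mode on one feature map.
#'
#' @param x 3-d array (H, W, C) feature map.
#' @param stage parameters from [dccStage()].
#' @param path `"merged"` (sum), `"single"` or `"stacked"`.
#' @return 3-d array (H, W, width).
#' @export
semanticChannel <- function(x, stage, path = c("merged", "single", "stacked")) {
  path <- match.arg(path)
  xb <- asBatch(x)
  a <- blockFwd(stage$semA, xb, FALSE)$y
  b <- blockFwd(stage$semB2, blockFwd(stage$semB1, xb, FALSE)$y, FALSE)$y
  out <- switch(path, merged = a + b, single = a, stacked = b)
  array(out, dim(out)[1:3])
}

#' Texture channel of a DCC stage
#'
#' Two asymmetric convolutions (kx1 then 1xk, stride 1, same padding) whose
#' output matches the semantic channel's shape; the factorized pair costs
#' 2k Cin Cout weights versus k^2 Cin Cout for a full kxk kernel.
#'
#' @inheritParams semanticChannel
#' @return 3-d array (H, W, width).
#' @export
textureChannel <- function(x, stage) {
  xb <- asBatch(x)
  out <- blockFwd(stage$texB, blockFwd(stage$texA, xb, FALSE)$y, FALSE)$y
  array(out, dim(out)[1:3])
}

#' Global channel attention on a fused feature pair
#'
#' Fuses `semantic + texture` element-wise into I', squeezes it to the
#' channel descriptor Is (per-channel spatial mean), condenses channel
#' depth with a 1x1 convolution into Ia, and forms the refined map
#' `sigmoid(Ia) x Is` (an outer/broadcast product over channels and space)
#' which multiplies I' on its way to the decoder.
#'
#' @param semantic,texture 3-d arrays (H, W, C) of identical shape.
#' @param weights 1x1 convolution weights, numeric length C; `NULL` means
#'   all zeros (so the attention map is 0.5 everywhere).
#' @param bias 1x1 convolution bias.
#' @return list with `output` (H, W, C), `attention` (H, W, strictly in
#'   (0, 1)), `descriptor` (length C) and `fused` (H, W, C).
#' @export
gca <- function(semantic, texture, weights = NULL, bias = 0) {
  if (!identical(dim(semantic), dim(texture)))
    stop("semantic and texture shapes differ")
  d <- dim(semantic)
  C <- d[3]
  if (is.null(weights)) weights <- numeric(C)
  stopifnot(length(weights) == C)
  p <- list(w = array(weights, c(1, 1, C, 1)), b = bias)
  fused <- asBatch(semantic + texture)
  g <- gcaFwd(p, fused)
  list(output = array(g$y, d), attention = matrix(g$cache$A, d[1], d[2]),
       descriptor = as.numeric(g$cache$Is), fused = array(fused, d))
}
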