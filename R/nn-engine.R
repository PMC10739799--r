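# Compact CPU training engine for the segmentation networks. Feature maps
# are 4-d arrays (H, W, C, N); convolutions, pooling and bilinear
# upsampling run in compiled code (src/nn_ops.cpp); batch normalization,
# activations, the attention module and Adam live here. Every layer has an
# explicit forward/backward pair; there is no general autograd.

HE_EPS <- 1e-5   # batch-norm epsilon
BN_MOM <- 0.3    # running-statistics momentum; high enough that the
                 # running estimates track the batch statistics within a
                 # few mini-batches even in short scaled-down runs

convInit <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

# conv -> BN -> ReLU with optional identity/projection residual shortcut
blockInit <- function(kh, kw, cin, cout, residual = TRUE) {
  p <- convInit(kh, kw, cin, cout)
  p$gamma <- rep(1, cout); p$beta <- numeric(cout)
  p$rm <- numeric(cout); p$rv <- rep(1, cout)
  p$residual <- residual
  if (residual && cin != cout) {
    pr <- convInit(1, 1, cin, cout)
    p$pw <- pr$w; p$pb <- pr$b
  }
  p
}

asBatch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

chSum <- function(a) {
  d <- dim(a)
  cs <- colSums(matrix(a, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}

chBcast <- function(v, d) rep(v, each = d[1] * d[2])  # recycles over N

bnFwd <- function(p, z, train) {
  d <- dim(z)
  n <- d[1] * d[2] * d[4]
  if (train) {
    m <- chSum(z) / n
    v <- chSum(z * z) / n - m^2
    p$rm <- (1 - BN_MOM) * p$rm + BN_MOM * m
    p$rv <- (1 - BN_MOM) * p$rv + BN_MOM * v
  } else {
    m <- p$rm; v <- p$rv
  }
  inv <- 1 / sqrt(v + HE_EPS)
  xhat <- (z - chBcast(m, d)) * chBcast(inv, d)
  y <- xhat * chBcast(p$gamma, d) + chBcast(p$beta, d)
  list(y = y, p = p, cache = list(xhat = xhat, inv = inv, n = n, d = d))
}

bnBwd <- function(p, cache, dy) {
  d <- cache$d
  dgamma <- chSum(dy * cache$xhat)
  dbeta <- chSum(dy)
  dxhat <- dy * chBcast(p$gamma, d)
  s1 <- chSum(dxhat)
  s2 <- chSum(dxhat * cache$xhat)
  dz <- chBcast(cache$inv / cache$n, d) *
    (cache$n * dxhat - chBcast(s1, d) - cache$xhat * chBcast(s2, d))
  dim(dz) <- d
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

blockFwd <- function(p, x, train) {
  z <- nn_conv_fwd(x, p$w, p$b)
  bn <- bnFwd(p, z, train)
  p <- bn$p
  h <- bn$y
  proj <- !is.null(p$pw)
  if (p$residual) {
    s <- if (proj) nn_conv_fwd(x, p$pw, p$pb) else x
    h <- h + s
  }
  dim(h) <- dim(z)
  y <- h * (h > 0)
  list(y = y, p = p,
       cache = list(x = x, bn = bn$cache, rmask = h > 0, proj = proj))
}

blockBwd <- function(p, cache, dy) {
  dh <- dy * cache$rmask
  dim(dh) <- dim(dy)
  g <- list()
  dxr <- NULL
  if (p$residual) {
    if (cache$proj) {
      r <- nn_conv_bwd(cache$x, p$pw, dh)
      dxr <- r$dx; g$pw <- r$dw; g$pb <- r$db
    } else dxr <- dh
  }
  bb <- bnBwd(p, cache$bn, dh)
  cc <- nn_conv_bwd(cache$x, p$w, bb$dz)
  dx <- cc$dx
  if (!is.null(dxr)) dx <- dx + dxr
  g$w <- cc$dw; g$b <- cc$db; g$gamma <- bb$dgamma; g$beta <- bb$dbeta
  list(dx = dx, grads = g)
}

gcaInit <- function(c) {
  p <- convInit(1, 1, c, 1)
  list(w = p$w, b = p$b)
}

# Global channel attention: fuse = semantic + texture has already happened;
# Is = per-channel spatial mean (squeeze), Ia = 1x1 conv to one channel,
# refined map = sigmoid(Ia) x Is (outer/broadcast product), output =
# refined map * fused.
gcaFwd <- function(p, fused) {
  d <- dim(fused)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ia <- nn_conv_fwd(fused, p$w, p$b)            # (H, W, 1, N)
  A <- 1 / (1 + exp(-Ia))
  Is <- matrix(chSumPerSample(fused), C, N) / (H * W)
  aexp <- A[, , rep(1L, C), , drop = FALSE]
  dim(aexp) <- d
  isexp <- array(rep(as.vector(Is), each = H * W), dim = d)
  refined <- aexp * isexp
  y <- refined * fused
  list(y = y, cache = list(fused = fused, A = A, Is = Is, aexp = aexp,
                           isexp = isexp))
}

# per-(channel, sample) sums, returned as C x N
chSumPerSample <- function(a) {
  d <- dim(a)
  colSums(matrix(a, d[1] * d[2], d[3] * d[4]))
}

gcaBwd <- function(p, cache, dy) {
  d <- dim(cache$fused)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  fused <- cache$fused
  dfused <- dy * cache$aexp * cache$isexp
  dIs <- matrix(chSumPerSample(dy * cache$aexp * fused), C, N)
  dfused <- dfused + array(rep(as.vector(dIs), each = H * W) / (H * W), dim = d)
  m <- dy * cache$isexp * fused
  dA <- m[, , 1L, , drop = FALSE]
  if (C > 1L) for (cc in 2:C) dA <- dA + m[, , cc, , drop = FALSE]
  dIa <- dA * cache$A * (1 - cache$A)
  dim(dIa) <- c(H, W, 1L, N)
  r <- nn_conv_bwd(fused, p$w, dIa)
  dfused <- dfused + r$dx
  list(dfused = dfused, grads = list(w = r$dw, b = r$db))
}

# ---- concat / split along the channel dimension ---------------------------

ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

csplit <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- Adam ------------------------------------------------------------------

# Parameters are nested named lists; gradients mirror them but only contain
# trainable leaves (running BN statistics are absent and therefore skipped).
adamStep <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  walk <- function(p, g, s) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], if (is.null(s[[nm]])) list() else s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      } else {
        gv <- g[[nm]]
        if (is.null(s[[nm]])) s[[nm]] <- list(m = gv * 0, v = gv * 0)
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * gv
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * gv^2
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

# Sum of two gradient trees with identical structure
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) gradAdd(a[[nm]], b[[nm]])
               else if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
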