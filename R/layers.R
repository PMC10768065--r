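# Elementary differentiable layers.
#
# Every layer is a plain list with a `type`, a `par` sublist holding its
# learnable arrays, and layer metadata.  `layer_fw(layer, x, training)`
# returns list(y, cache); `layer_bw(layer, cache, gy)` returns
# list(gx, grads) with `grads` mirroring the names in `par`.  Composite
# blocks (conv block, DA, RDC, SCA, the network) are built from these and
# follow the same protocol, with nested `grads`.

new_conv2d <- function(kh, kw, cin, cout, groups = 1L, pad = 0L, dil = 1L,
                       bias = FALSE) {
  cpg <- cin %/% groups
  if (cpg * groups != cin) stop("conv2d: cin not divisible by groups")
  fan_in <- kh * kw * cpg
  par <- list(w = array(init_uniform(kh * kw * cpg * cout, fan_in),
                        c(kh, kw, cpg, cout)))
  if (bias) par$b <- init_uniform(cout, fan_in)
  list(type = "conv2d", par = par, pad = as.integer(pad),
       dil = as.integer(dil), groups = as.integer(groups))
}

conv2d_fw_ <- function(l, x) {
  .conv2d_fw(x, l$par$w, l$par$b, l$pad, l$dil, l$groups)
}

conv2d_bw_ <- function(l, x, gy) {
  r <- .conv2d_bw(x, l$par$w, gy, !is.null(l$par$b), l$pad, l$dil, l$groups)
  grads <- list(w = r$gw)
  if (!is.null(l$par$b)) grads$b <- r$gb
  list(gx = r$gx, grads = grads)
}

# --- batch normalization (affine), used inside conv blocks ------------------

new_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", par = list(gamma = rep(1, c), beta = rep(0, c)),
       run_mean = rep(0, c), run_var = rep(1, c),
       eps = eps, momentum = momentum)
}

# per-(c,b)-column view helpers: x has dim (H, W, C, B)
.chan_mat <- function(x) {
  d <- dim(x)
  matrix(x, nrow = d[1] * d[2], ncol = d[3] * d[4])
}

bn_fw_ <- function(l, x, training) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  xm <- .chan_mat(x)
  if (training) {
    cm <- .colMeans(xm, hw, C * B)
    cm2 <- .colMeans(xm * xm, hw, C * B)
    m <- .rowMeans(matrix(cm, C, B), C, B)
    v <- .rowMeans(matrix(cm2, C, B), C, B) - m^2
  } else {
    m <- l$run_mean
    v <- l$run_var
  }
  ivar <- 1 / sqrt(v + l$eps)
  ci <- rep(seq_len(C), times = B)
  xhat <- (xm - rep(m[ci], each = hw)) * rep(ivar[ci], each = hw)
  y <- rep(l$par$gamma[ci], each = hw) * xhat + rep(l$par$beta[ci], each = hw)
  dim(y) <- d
  cache <- list(xhat = xhat, ivar = ivar, ci = ci, d = d,
                batch_mean = if (training) m, batch_var = if (training) v)
  list(y = y, cache = cache)
}

# update running statistics (training mode); returns the modified layer
bn_update_stats <- function(l, cache) {
  n <- cache$d[1] * cache$d[2] * cache$d[4]
  unb <- if (n > 1) n / (n - 1) else 1
  l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * cache$batch_mean
  l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * cache$batch_var * unb
  l
}

bn_bw_ <- function(l, cache, gy) {
  d <- cache$d
  hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  n <- hw * B
  ci <- cache$ci
  gym <- .chan_mat(gy)
  xhat <- cache$xhat
  # per-channel reductions pooled over batch
  s1 <- .rowMeans(matrix(.colSums(gym, hw, C * B), C, B), C, B) * B
  s2 <- .rowMeans(matrix(.colSums(gym * xhat, hw, C * B), C, B), C, B) * B
  ggamma <- s2
  gbeta <- s1
  coef <- l$par$gamma * cache$ivar / n
  gx <- rep(coef[ci], each = hw) *
    (n * gym - rep(s1[ci], each = hw) - xhat * rep(s2[ci], each = hw))
  dim(gx) <- d
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

# --- group normalization (groups = 4, no affine parameters) -----------------

new_gn <- function(c, groups = 4L, eps = 1e-5) {
  if (c %% groups != 0)
    stop("group norm: channel count must be divisible by ", groups)
  list(type = "gn", par = list(), groups = as.integer(groups), eps = eps)
}

gn_fw_ <- function(l, x) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  G <- l$groups; cpg <- C %/% G
  # view as (hw*cpg) x (G*B): channels are contiguous, so each group of cpg
  # consecutive (c,b) columns is one normalization unit
  xm <- matrix(x, nrow = hw * cpg, ncol = G * B)
  n <- hw * cpg
  m <- .colMeans(xm, n, G * B)
  v <- .colMeans(xm * xm, n, G * B) - m^2
  ivar <- 1 / sqrt(v + l$eps)
  xhat <- (xm - rep(m, each = n)) * rep(ivar, each = n)
  y <- xhat
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, ivar = ivar, d = d, n = n))
}

gn_bw_ <- function(l, cache, gy) {
  d <- cache$d; n <- cache$n
  gym <- matrix(gy, nrow = n)
  xhat <- cache$xhat
  s1 <- .colSums(gym, n, ncol(gym))
  s2 <- .colSums(gym * xhat, n, ncol(gym))
  gx <- rep(cache$ivar / n, each = n) *
    (n * gym - rep(s1, each = n) - xhat * rep(s2, each = n))
  dim(gx) <- d
  list(gx = gx, grads = list())
}

# --- pooling / upsampling ---------------------------------------------------

maxpool2_fw_ <- function(x) .maxpool2_fw(x)
maxpool2_bw_ <- function(cache, gy) .maxpool2_bw(gy, cache$idx, cache$xdim)
upsample2_fw_ <- function(x) .upsample2_fw(x)
upsample2_bw_ <- function(gy) .upsample2_bw(gy)
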