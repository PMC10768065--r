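# The network's building blocks: the basic Conv2d block and the three
# bespoke attention/refinement blocks. Each has a state constructor, a
# public functional operator on feature maps, and internal fw/bw passes
# used by the training loop.

# ---------------------------------------------------------------------------
# Conv2d block: 3x3 conv (stride 1, padding 1) + batch normalization + GELU
# ---------------------------------------------------------------------------

#' Conv2d block state
#'
#' The basic feature-extraction unit: a 3x3 convolution (stride 1, padding 1)
#' followed by batch normalization and a GELU activation. Encoder blocks are
#' bias-free (the normalization shift absorbs the bias); decoder blocks carry
#' a bias, matching the complexity accounting of the reference network.
#'
#' @param in_channels,out_channels positive channel counts.
#' @param bias should the convolution carry a bias vector?
#' @return a conv-block state usable with [conv2d_block()].
#' @export
conv_block_state <- function(in_channels, out_channels, bias = FALSE) {
  if (out_channels < 1) stop("conv block: out_channels must be positive")
  structure(list(type = "conv_block",
                 conv = new_conv2d(3, 3, in_channels, out_channels,
                                   pad = 1, bias = bias),
                 bn = new_bn(out_channels)),
            class = "ws_block")
}

conv_block_fw <- function(l, x, training = FALSE) {
  a <- conv2d_fw_(l$conv, x)
  nb <- bn_fw_(l$bn, a, training)
  if (training) l$bn <- bn_update_stats(l$bn, nb$cache)
  phi <- pnorm(nb$y)
  list(y = nb$y * phi,
       cache = list(x = x, bn = nb$cache, pre = nb$y, phi = phi),
       layer = l)
}

conv_block_bw <- function(l, cache, gy) {
  g <- gy * gelu_grad_phi(cache$pre, cache$phi)
  bb <- bn_bw_(l$bn, cache$bn, g)
  cb <- conv2d_bw_(l$conv, cache$x, bb$gx)
  list(gx = cb$gx, grads = list(conv = cb$grads, bn = bb$grads))
}

#' Apply a Conv2d block
#'
#' @param x feature map (`H x W x C x B` array, see [feature_map()]).
#' @param state a [conv_block_state()]; if `NULL`, a fresh state with
#'   `out_channels` output channels is drawn from the current RNG.
#' @param out_channels output channel count used when `state` is `NULL`.
#' @return a feature map with the same spatial size and `out_channels`
#'   channels. Normalization runs in inference mode (running statistics).
#' @examples
#' x <- feature_map(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
#' y <- conv2d_block(x, out_channels = 8)
#' dim(y)
#' @export
conv2d_block <- function(x, state = NULL, out_channels = NULL) {
  x <- feature_map(x)
  if (is.null(state)) {
    if (is.null(out_channels) || out_channels < 1)
      stop("conv2d_block: `out_channels` must be a positive integer")
    state <- conv_block_state(dim(x)[3], out_channels)
  }
  conv_block_fw(state, x, training = FALSE)$y
}

# ---------------------------------------------------------------------------
# Dual attention (DA): external-attention memory units + channel gating
# ---------------------------------------------------------------------------

#' Dual attention block state
#'
#' The dual attention block explores dataset-level structure with two
#' external memory units of shape `4C x C` (an attention mechanism linear in
#' the pixel count), and complements it with a channel-gating branch (global
#' average pooling, a shared 3-tap 1-D convolution across channels, and a
#' sigmoid gate). Both branches join the identity path under a GELU.
#'
#' @param channels channel count `C`; must be divisible by 4 (the group
#'   normalization inside the block uses 4 groups).
#' @return a DA state usable with [dual_attention()].
#' @export
da_state <- function(channels) {
  C <- as.integer(channels)
  if (C %% 4L != 0L) stop("dual attention: channels must be divisible by 4")
  structure(list(
    type = "da",
    par = list(
      mem_k = matrix(rnorm(C * 4 * C, sd = 1 / sqrt(C)), C, 4 * C),
      mem_v = matrix(rnorm(4 * C * C, sd = 1 / sqrt(C)), 4 * C, C),
      mem_v_b = rep(0, C),
      c1d = init_uniform(3, 3)
    ),
    proj_in = new_conv2d(1, 1, C, C, bias = FALSE),
    gn_in = new_gn(C),
    proj_out = new_conv2d(1, 1, C, C, bias = FALSE),
    gn_out = new_gn(C),
    channels = C
  ), class = "ws_block")
}

# 3-tap single-channel 1-D convolution over the channel axis (zero padded);
# g is a C x B matrix of pooled channel descriptors.
c1d_fw <- function(w, g) {
  C <- nrow(g)
  up <- rbind(g[-1, , drop = FALSE], 0)    # g[c+1]
  dn <- rbind(0, g[-C, , drop = FALSE])    # g[c-1]
  list(z = w[1] * dn + w[2] * g + w[3] * up, up = up, dn = dn)
}

c1d_bw <- function(w, cache, g, gz) {
  C <- nrow(g)
  gw <- c(sum(gz * cache$dn), sum(gz * g), sum(gz * cache$up))
  gg <- w[1] * rbind(gz[-1, , drop = FALSE], 0) +
    w[2] * gz +
    w[3] * rbind(0, gz[-C, , drop = FALSE])
  list(gw = gw, gg = gg)
}

# reshape (H,W,C,B) <-> ((H*W*B) x C) pixel matrices for the memory matmuls
.pix_mat <- function(x, N, C, B) {
  matrix(aperm(array(x, c(N, C, B)), c(1, 3, 2)), N * B, C)
}

.pix_arr <- function(m, N, C, B, d) {
  array(aperm(array(m, c(N, B, C)), c(1, 3, 2)), d)
}

da_fw <- function(l, x, want_attention = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  if (C != l$channels) stop("dual attention: channel mismatch")
  N <- H * W
  # branch 1: external attention against the memory units (all images of
  # the batch share one pixel matrix, so each product is a single GEMM)
  p1 <- conv2d_fw_(l$proj_in, x)
  g1 <- gn_fw_(l$gn_in, p1)
  Xin <- .pix_mat(g1$y, N, C, B)
  A <- softmax_rows(Xin %*% l$par$mem_k)
  Y <- A %*% l$par$mem_v + rep(l$par$mem_v_b, each = N * B)
  y1 <- .pix_arr(Y, N, C, B, d)
  p2 <- conv2d_fw_(l$proj_out, y1)
  g2 <- gn_fw_(l$gn_out, p2)
  # branch 2: global average pooling -> shared 1-D conv -> sigmoid gate
  hw <- N
  gap <- matrix(.colMeans(.chan_mat(x), hw, C * B), C, B)
  cc <- c1d_fw(l$par$c1d, gap)
  gate <- sigmoid(cc$z)
  xm <- .chan_mat(x)
  out2 <- xm * rep(as.vector(gate), each = hw)
  dim(out2) <- d
  pre <- g2$y + out2 + x
  phi <- pnorm(pre)
  y <- pre * phi
  cache <- list(x = x, p1x = x, gn_in = g1$cache, Xin = Xin, A = A,
                y1 = y1, p2x = y1, gn_out = g2$cache, gap = gap, cc = cc,
                gate = gate, pre = pre, phi = phi, d = d)
  out <- list(y = y, cache = cache)
  if (want_attention) out$attention <- array(A, c(N, B, 4 * C))
  out
}

da_bw <- function(l, cache, gy) {
  d <- cache$d
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  N <- H * W
  gpre <- gy * gelu_grad_phi(cache$pre, cache$phi)
  # branch 1
  gb1 <- gn_bw_(l$gn_out, cache$gn_out, gpre)
  cb1 <- conv2d_bw_(l$proj_out, cache$p2x, gb1$gx)
  gY <- .pix_mat(cb1$gx, N, C, B)
  A <- cache$A
  gbv <- .colSums(gY, N * B, C)
  gwv <- crossprod(A, gY)
  gA <- tcrossprod(gY, l$par$mem_v)
  gX1 <- A * (gA - rowSums(gA * A))
  gwk <- crossprod(cache$Xin, gX1)
  gXin <- .pix_arr(tcrossprod(gX1, l$par$mem_k), N, C, B, d)
  gg1 <- gn_bw_(l$gn_in, cache$gn_in, gXin)
  cb0 <- conv2d_bw_(l$proj_in, cache$p1x, gg1$gx)
  # branch 2
  hw <- N
  xm <- .chan_mat(cache$x)
  gm <- .chan_mat(gpre)
  ggate <- matrix(.colSums(gm * xm, hw, C * B), C, B)
  gx2 <- gm * rep(as.vector(cache$gate), each = hw)
  gz <- ggate * cache$gate * (1 - cache$gate)
  cb2 <- c1d_bw(l$par$c1d, cache$cc, cache$gap, gz)
  gx_gap <- rep(as.vector(cb2$gg) / hw, each = hw)
  gx <- cb0$gx + gpre
  gx <- gx + array(gx2 + gx_gap, d)
  list(gx = gx,
       grads = list(mem_k = gwk, mem_v = gwv, mem_v_b = gbv, c1d = cb2$gw,
                    proj_in = cb0$grads, proj_out = cb1$grads))
}

#' Apply the dual attention block
#'
#' Branch one projects the input, queries a `4C x C` key memory, softmax-
#' normalizes each pixel's weights over the 4C memory slots, reads a value
#' memory and projects back. Branch two rescales channels with a gate
#' obtained from global average pooling and a shared 3-tap 1-D convolution.
#' The output is `GELU(branch1 + branch2 + x)` and keeps the input shape.
#'
#' @param x feature map with channel count divisible by 4.
#' @param state a [da_state()]; if `NULL`, drawn fresh from the current RNG.
#' @return a feature map with the shape of `x`.
#' @export
dual_attention <- function(x, state = NULL) {
  x <- feature_map(x)
  if (dim(x)[3] %% 4 != 0)
    stop("dual_attention: channel count must be divisible by 4")
  if (is.null(state)) state <- da_state(dim(x)[3])
  da_fw(state, x)$y
}

# ---------------------------------------------------------------------------
# Refinement dilated conv (RDC): split / parallel dilation / fuse
# ---------------------------------------------------------------------------

rdc_rates <- c(1L, 2L, 5L, 8L)

#' Refinement dilated conv block state
#'
#' The input is split into four equal channel groups; group k passes through
#' a depthwise 3x3 convolution with dilation rate 1, 2, 5 or 8 (padding
#' equal to the rate, so spatial size is preserved). The groups are
#' concatenated and fused by a pointwise convolution with group
#' normalization and GELU, mapping to `out_channels`.
#'
#' @param in_channels channel count of the input; must be divisible by 4.
#' @param out_channels channel count after the pointwise fusion.
#' @return an RDC state usable with [refinement_dilated_conv()].
#' @export
rdc_state <- function(in_channels, out_channels) {
  cin <- as.integer(in_channels)
  if (cin %% 4L != 0L) stop("RDC: in_channels must be divisible by 4")
  if (out_channels < 1) stop("RDC: out_channels must be positive")
  g <- cin %/% 4L
  branches <- lapply(rdc_rates, function(r)
    new_conv2d(3, 3, g, g, groups = g, pad = r, dil = r, bias = TRUE))
  names(branches) <- paste0("b", seq_len(4))
  structure(c(list(type = "rdc"),
              branches,
              list(fuse = new_conv2d(1, 1, cin, out_channels, bias = FALSE),
                   gn = new_gn(out_channels),
                   in_channels = cin, out_channels = as.integer(out_channels))),
            class = "ws_block")
}

rdc_fw <- function(l, x) {
  d <- dim(x)
  C <- d[3]
  if (C != l$in_channels) stop("RDC: channel mismatch")
  g <- C %/% 4L
  parts <- vector("list", 4)
  cat_y <- array(0, c(d[1], d[2], C, d[4]))
  for (k in 1:4) {
    idx <- ((k - 1) * g + 1):(k * g)
    xk <- x[, , idx, , drop = FALSE]
    parts[[k]] <- xk
    cat_y[, , idx, ] <- conv2d_fw_(l[[paste0("b", k)]], xk)
  }
  f <- conv2d_fw_(l$fuse, cat_y)
  gn <- gn_fw_(l$gn, f)
  phi <- pnorm(gn$y)
  list(y = gn$y * phi,
       cache = list(parts = parts, cat_y = cat_y, gn = gn$cache,
                    pre = gn$y, phi = phi, d = d))
}

rdc_bw <- function(l, cache, gy) {
  g <- l$in_channels %/% 4L
  gpre <- gy * gelu_grad_phi(cache$pre, cache$phi)
  gg <- gn_bw_(l$gn, cache$gn, gpre)
  cf <- conv2d_bw_(l$fuse, cache$cat_y, gg$gx)
  d <- cache$d
  gx <- array(0, d)
  grads <- list(fuse = cf$grads)
  for (k in 1:4) {
    idx <- ((k - 1) * g + 1):(k * g)
    gk <- cf$gx[, , idx, , drop = FALSE]
    cb <- conv2d_bw_(l[[paste0("b", k)]], cache$parts[[k]], gk)
    gx[, , idx, ] <- cb$gx
    grads[[paste0("b", k)]] <- cb$grads
  }
  list(gx = gx, grads = grads)
}

#' Apply the refinement dilated conv block
#'
#' @param x feature map with channel count divisible by 4.
#' @param state an [rdc_state()]; if `NULL`, a fresh state mapping to
#'   `out_channels` is drawn from the current RNG.
#' @param out_channels output channels used when `state` is `NULL`.
#' @return a feature map with the same spatial size and `out_channels`
#'   channels.
#' @export
refinement_dilated_conv <- function(x, state = NULL, out_channels = NULL) {
  x <- feature_map(x)
  if (dim(x)[3] %% 4 != 0)
    stop("refinement_dilated_conv: channel count must be divisible by 4")
  if (is.null(state)) {
    if (is.null(out_channels) || out_channels < 1)
      stop("refinement_dilated_conv: `out_channels` must be positive")
    state <- rdc_state(dim(x)[3], out_channels)
  }
  rdc_fw(state, x)$y
}

# ---------------------------------------------------------------------------
# Spatial connectivity attention (SCA): one shared 7x7 dilation-3 gate
# ---------------------------------------------------------------------------

#' Spatial connectivity attention state
#'
#' A single 7x7 convolution (dilation 3, padding 9, 2 input channels, 1
#' output channel, with scalar bias) shared across every stage. For each
#' stage the channel-wise max and average maps are concatenated, convolved
#' by the shared kernel and squashed to a sigmoid gate `T`; the output is
#' `T * x + x`. The block owns 2*7*7 + 1 = 99 trainable scalars regardless
#' of the stage count.
#'
#' @return an SCA state usable with [spatial_connectivity_attention()].
#' @export
sca_state <- function() {
  structure(list(type = "sca",
                 shared = new_conv2d(7, 7, 2, 1, pad = 9, dil = 3,
                                     bias = TRUE)),
            class = "ws_block")
}

# channel-wise max and mean with argmax bookkeeping for the backward pass
.chan_max_mean <- function(x) {
  d <- dim(x)
  C <- d[3]
  m <- x[, , 1, , drop = FALSE]
  am <- array(1L, dim(m))
  if (C > 1) for (c in 2:C) {
    xc <- x[, , c, , drop = FALSE]
    upd <- xc > m
    m[upd] <- xc[upd]
    am[upd] <- c
  }
  mn <- x[, , 1, , drop = FALSE]
  if (C > 1) for (c in 2:C) mn <- mn + x[, , c, , drop = FALSE]
  mn <- mn / C
  list(max = m, mean = mn, argmax = am)
}

sca_fw <- function(l, stages) {
  n <- length(stages)
  if (n == 0) stop("spatial connectivity attention: empty stage list")
  bsz <- vapply(stages, function(s) dim(s)[4], numeric(1))
  if (length(unique(bsz)) != 1)
    stop("spatial connectivity attention: per-stage batch sizes differ")
  out <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    x <- stages[[i]]
    d <- dim(x)
    mm <- .chan_max_mean(x)
    bmap <- array(0, c(d[1], d[2], 2, d[4]))
    bmap[, , 1, ] <- mm$max
    bmap[, , 2, ] <- mm$mean
    s <- conv2d_fw_(l$shared, bmap)
    gate <- sigmoid(s)
    gv <- rep(as.vector(gate), times = d[3])
    dim(gv) <- c(d[1], d[2], d[4], d[3])
    gv <- aperm(gv, c(1, 2, 4, 3))
    out[[i]] <- x * (1 + gv)
    caches[[i]] <- list(x = x, bmap = bmap, gate = gate, gv = gv,
                        argmax = mm$argmax, d = d)
  }
  list(y = out, cache = caches)
}

sca_bw <- function(l, caches, gouts) {
  gw <- array(0, dim(l$shared$par$w))
  gb <- 0
  gx <- vector("list", length(caches))
  for (i in seq_along(caches)) {
    cc <- caches[[i]]
    d <- cc$d
    C <- d[3]
    go <- gouts[[i]]
    gxi <- go * (1 + cc$gv)
    ggate <- go[, , 1, , drop = FALSE] * cc$x[, , 1, , drop = FALSE]
    if (C > 1) for (c in 2:C)
      ggate <- ggate + go[, , c, , drop = FALSE] * cc$x[, , c, , drop = FALSE]
    gs <- ggate * cc$gate * (1 - cc$gate)
    cb <- conv2d_bw_(l$shared, cc$bmap, gs)
    gw <- gw + cb$grads$w
    gb <- gb + cb$grads$b
    gmax <- array(cb$gx[, , 1, ], c(d[1], d[2], d[4]))
    gmean <- array(cb$gx[, , 2, ] / C, c(d[1], d[2], d[4]))
    am <- array(cc$argmax, c(d[1], d[2], d[4]))
    for (c in seq_len(C)) {
      sel <- am == c
      add <- gmean
      add[sel] <- add[sel] + gmax[sel]
      gxi[, , c, ] <- gxi[, , c, ] + add
    }
    gx[[i]] <- gxi
  }
  list(gx = gx, grads = list(shared = list(w = gw, b = gb)))
}

#' Apply spatial connectivity attention to a list of stage outputs
#'
#' @param stage_outputs list of feature maps (one per encoder stage; any
#'   positive number of stages, six in the default network). All must share
#'   one batch size.
#' @param state an [sca_state()]; if `NULL`, drawn fresh from the current
#'   RNG.
#' @return a list of gated feature maps, each with the shape of its input.
#' @export
spatial_connectivity_attention <- function(stage_outputs, state = NULL) {
  if (!is.list(stage_outputs) || length(stage_outputs) == 0)
    stop("spatial_connectivity_attention: `stage_outputs` must be a ",
         "non-empty list of feature maps")
  stage_outputs <- lapply(stage_outputs, feature_map)
  if (is.null(state)) state <- sca_state()
  sca_fw(state, stage_outputs)$y
}
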