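# Independent dense-loop reference implementations of the blocks, written
# directly from their defining equations with explicit nested loops. They
# share nothing with the package's vectorized/GEMM forward passes and serve
# as oracles on small inputs.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_gelu <- function(x) x * pnorm(x)
oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# plain 2-D convolution, stride 1, zero padding, optional dilation/groups
oracle_conv2d <- function(x, w, b = NULL, pad = 0, dil = 1, groups = 1) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cpg <- dim(w)[3]; cout <- dim(w)[4]
  copg <- cout / groups
  y <- array(0, c(H, W, cout, B))
  for (bb in seq_len(B)) for (o in seq_len(cout)) {
    g <- ceiling(o / copg)
    for (h in seq_len(H)) for (wj in seq_len(W)) {
      acc <- if (is.null(b)) 0 else b[o]
      for (c in seq_len(cpg)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        ih <- h + (ki - 1) * dil - pad
        iw <- wj + (kj - 1) * dil - pad
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[ih, iw, (g - 1) * cpg + c, bb] * w[ki, kj, c, o]
      }
      y[h, wj, o, bb] <- acc
    }
  }
  y
}

# group normalization without affine parameters (4 groups)
oracle_groupnorm <- function(x, groups = 4, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]; cpg <- C / groups
  y <- x
  for (bb in seq_len(d[4])) for (g in seq_len(groups)) {
    idx <- ((g - 1) * cpg + 1):(g * cpg)
    v <- x[, , idx, bb]
    m <- mean(v)
    s <- mean((v - m)^2)
    y[, , idx, bb] <- (v - m) / sqrt(s + eps)
  }
  y
}

# Conv2d block in inference mode, from a conv_block_state
oracle_conv_block <- function(state, x) {
  a <- oracle_conv2d(x, state$conv$par$w, state$conv$par$b, pad = 1)
  bn <- state$bn
  y <- a
  for (c in seq_len(dim(a)[3]))
    y[, , c, ] <- bn$par$gamma[c] *
      (a[, , c, ] - bn$run_mean[c]) / sqrt(bn$run_var[c] + bn$eps) +
      bn$par$beta[c]
  oracle_gelu(y)
}

# Dual attention from a da_state: external-attention branch (project,
# multiply by the key memory, softmax over the 4C slots, read the value
# memory, project back) plus channel gating, summed with the identity under
# a GELU.
oracle_dual_attention <- function(state, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  N <- H * W
  out <- array(0, d)
  for (bb in seq_len(B)) {
    xb <- x[, , , bb, drop = FALSE]
    p1 <- oracle_conv2d(xb, state$proj_in$par$w)
    p1 <- oracle_groupnorm(p1)
    # pixel matrix, column-major pixel order
    X <- matrix(0, N, C)
    for (c in seq_len(C)) for (wj in seq_len(W)) for (h in seq_len(H))
      X[h + H * (wj - 1), c] <- p1[h, wj, c, 1]
    X1 <- matrix(0, N, 4 * C)
    for (n in seq_len(N)) for (m in seq_len(4 * C))
      X1[n, m] <- sum(X[n, ] * state$par$mem_k[, m])
    A <- matrix(0, N, 4 * C)
    for (n in seq_len(N)) {
      e <- exp(X1[n, ] - max(X1[n, ]))
      A[n, ] <- e / sum(e)
    }
    Y <- matrix(0, N, C)
    for (n in seq_len(N)) for (c in seq_len(C))
      Y[n, c] <- sum(A[n, ] * state$par$mem_v[, c]) + state$par$mem_v_b[c]
    y1 <- array(0, c(H, W, C, 1))
    for (c in seq_len(C)) for (wj in seq_len(W)) for (h in seq_len(H))
      y1[h, wj, c, 1] <- Y[h + H * (wj - 1), c]
    out1 <- oracle_groupnorm(oracle_conv2d(y1, state$proj_out$par$w))
    # channel gate: global average pool -> 3-tap 1-D conv -> sigmoid
    gap <- numeric(C)
    for (c in seq_len(C)) gap[c] <- mean(xb[, , c, 1])
    z <- numeric(C)
    for (c in seq_len(C)) {
      z[c] <- state$par$c1d[2] * gap[c] +
        (if (c > 1) state$par$c1d[1] * gap[c - 1] else 0) +
        (if (c < C) state$par$c1d[3] * gap[c + 1] else 0)
    }
    gate <- oracle_sigmoid(z)
    for (c in seq_len(C))
      out[, , c, bb] <- oracle_gelu(out1[, , c, 1] +
                                      gate[c] * xb[, , c, 1] +
                                      xb[, , c, 1])
  }
  out
}

# RDC from an rdc_state: channel split, depthwise dilated branches with
# rates 1/2/5/8, concat, pointwise fuse, group norm, GELU.
oracle_rdc <- function(state, x) {
  d <- dim(x)
  C <- d[3]; g <- C / 4
  rates <- c(1, 2, 5, 8)
  cat_y <- array(0, d)
  for (k in 1:4) {
    idx <- ((k - 1) * g + 1):(k * g)
    br <- state[[paste0("b", k)]]
    cat_y[, , idx, ] <- oracle_conv2d(x[, , idx, , drop = FALSE],
                                      br$par$w, br$par$b,
                                      pad = rates[k], dil = rates[k],
                                      groups = g)
  }
  f <- oracle_conv2d(cat_y, state$fuse$par$w)
  oracle_gelu(oracle_groupnorm(f))
}

# SCA from an sca_state applied to a list of stage outputs
oracle_sca <- function(state, stages) {
  lapply(stages, function(x) {
    d <- dim(x)
    H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
    out <- x
    for (bb in seq_len(B)) {
      bmap <- array(0, c(H, W, 2, 1))
      for (h in seq_len(H)) for (wj in seq_len(W)) {
        bmap[h, wj, 1, 1] <- max(x[h, wj, , bb])
        bmap[h, wj, 2, 1] <- mean(x[h, wj, , bb])
      }
      s <- oracle_conv2d(bmap, state$shared$par$w, state$shared$par$b,
                         pad = 9, dil = 3)
      gate <- oracle_sigmoid(s[, , 1, 1])
      for (c in seq_len(C))
        out[, , c, bb] <- gate * x[, , c, bb] + x[, , c, bb]
    }
    out
  })
}

# 4-connected component count of one label in a mask (flood fill)
count_components <- function(mask, lab) {
  m <- mask == lab
  visited <- matrix(FALSE, nrow(m), ncol(m))
  n <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && !visited[i, j]) {
      n <- n + 1
      stack <- list(c(i, j))
      visited[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          a <- p[1] + dd[1]; b <- p[2] + dd[2]
          if (a >= 1 && a <= nrow(m) && b >= 1 && b <= ncol(m) &&
              m[a, b] && !visited[a, b]) {
            visited[a, b] <- TRUE
            stack[[length(stack) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  n
}

# central-difference numeric gradient of scalar f at x
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small training pairs from the synthetic generator (preprocessed)
make_training_pairs <- function(n, size, seed0 = 100, n_crops = 2,
                                n_weeds = 6, crop_r = c(8, 12),
                                weed_r = c(2, 4)) {
  lapply(seq_len(n), function(i) {
    sp <- scene_spec(size = c(size, size), n_crops = n_crops,
                     n_weeds = n_weeds, crop_radius_range = crop_r,
                     weed_radius_range = weed_r, seed = seed0 + i)
    sc <- generate_synthetic_scene(sp)
    pp <- preprocess(sc$image, sc$mask, size = c(size, size))
    list(image = pp$image, mask = pp$mask)
  })
}
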