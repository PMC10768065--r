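# The four building blocks: shape contracts, forced-by-zero behaviour,
# equivalence with independent dense-loop oracles, and differentiability.

zero_params <- function(state) {
  flat <- weedseg:::collect_params(state)
  weedseg:::set_params(state, lapply(flat, function(p) p * 0))
}

test_that("conv2d block: shape contract, zeros, and loop oracle", {
  set.seed(1)
  x <- feature_map(array(rnorm(16 * 16 * 3), c(16, 16, 3, 1)))
  y <- conv2d_block(x, out_channels = 8)
  expect_identical(dim(y), c(16L, 16L, 8L, 1L))
  expect_true(all(is.finite(y)))
  expect_error(conv2d_block(x, out_channels = 0), "positive")

  st <- conv_block_state(3, 8)
  expect_equal(conv2d_block(x, zero_params(st)), array(0, c(16, 16, 8, 1)))

  # hand-set kernel, inference-mode norm with identity affine
  st <- conv_block_state(1, 1, bias = TRUE)
  st$conv$par$w[] <- rnorm(9)
  st$conv$par$b[] <- 0.3
  xs <- feature_map(array(rnorm(9), c(3, 3, 1, 1)))
  expect_equal(conv2d_block(xs, st), oracle_conv_block(st, xs),
               tolerance = 1e-5)
})

test_that("dual attention: shape, zeros, softmax rows, loop oracle", {
  set.seed(2)
  x <- feature_map(array(rnorm(16 * 16 * 8), c(16, 16, 8, 1)))
  st <- da_state(8)
  y <- dual_attention(x, st)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(dual_attention(array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))),
               "divisible by 4")

  # all weights zero: branch 1 dies, branch 2 halves, GELU(1.5 x)
  y0 <- dual_attention(x, zero_params(st))
  expect_equal(y0, 1.5 * x * pnorm(1.5 * x), tolerance = 1e-12)

  # each pixel's attention over the 4C memory slots is a simplex weight
  fwa <- weedseg:::da_fw(st, x, want_attention = TRUE)
  A <- fwa$cache$A
  expect_true(all(A > 0))
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)

  # dense-loop oracle on a tiny input, including a batch axis
  set.seed(3)
  xt <- feature_map(array(rnorm(2 * 2 * 4 * 2), c(2, 2, 4, 2)))
  stt <- da_state(4)
  expect_equal(dual_attention(xt, stt), oracle_dual_attention(stt, xt),
               tolerance = 1e-5)
})

test_that("refinement dilated conv: shape, zeros, rates, loop oracle", {
  set.seed(4)
  x <- feature_map(array(rnorm(32 * 32 * 32), c(32, 32, 32, 1)))
  st <- rdc_state(32, 48)
  y <- refinement_dilated_conv(x, st)
  expect_identical(dim(y), c(32L, 32L, 48L, 1L))
  expect_error(refinement_dilated_conv(
    array(rnorm(8 * 8 * 6), c(8, 8, 6, 1)), out_channels = 8),
    "divisible by 4")

  expect_equal(refinement_dilated_conv(x, zero_params(st)),
               array(0, c(32, 32, 48, 1)))

  # the four branches carry dilation (and padding) rates 1, 2, 5, 8
  expect_identical(vapply(paste0("b", 1:4), function(b) st[[b]]$dil,
                          integer(1), USE.NAMES = FALSE),
                   c(1L, 2L, 5L, 8L))

  # C = 4: one channel per group; delta kernels + identity fuse reduce the
  # block to GELU(groupnorm(x))
  st4 <- rdc_state(4, 4)
  for (k in 1:4) {
    st4[[paste0("b", k)]]$par$w[] <- 0
    st4[[paste0("b", k)]]$par$w[2, 2, 1, 1] <- 1
    st4[[paste0("b", k)]]$par$b[] <- 0
  }
  st4$fuse$par$w[] <- 0
  for (c in 1:4) st4$fuse$par$w[1, 1, c, c] <- 1
  xs <- feature_map(array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)))
  ref <- oracle_gelu(oracle_groupnorm(xs))
  expect_equal(refinement_dilated_conv(xs, st4), ref, tolerance = 1e-5)

  # general loop oracle
  set.seed(5)
  xt <- feature_map(array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2)))
  stt <- rdc_state(8, 8)
  expect_equal(refinement_dilated_conv(xt, stt), oracle_rdc(stt, xt),
               tolerance = 1e-5)
})

test_that("spatial connectivity attention: shapes, gates, sharing, oracle", {
  set.seed(6)
  shapes <- list(c(16, 16, 8, 1), c(8, 8, 16, 1), c(4, 4, 24, 1))
  stages <- lapply(shapes, function(s) array(rnorm(prod(s)), s))
  st <- sca_state()
  out <- spatial_connectivity_attention(stages, st)
  for (i in seq_along(out)) expect_identical(dim(out[[i]]), dim(stages[[i]]))

  expect_error(spatial_connectivity_attention(list()), "non-empty")
  bad <- list(array(rnorm(32), c(4, 4, 2, 1)), array(rnorm(64), c(4, 4, 2, 2)))
  expect_error(spatial_connectivity_attention(bad, st), "batch")

  # zero kernel and bias: every gate is 1/2, output 1.5 x
  out0 <- spatial_connectivity_attention(stages, zero_params(st))
  for (i in seq_along(out0))
    expect_equal(out0[[i]], 1.5 * stages[[i]], tolerance = 1e-12)

  # one shared kernel regardless of stage count
  expect_identical(count_parameters(st), 99)

  # gates lie strictly in (0,1): nonnegative input maps into [x, 2x]
  xp <- abs(stages[[1]])
  op <- spatial_connectivity_attention(list(xp), st)[[1]]
  expect_true(all(op >= xp - 1e-12) && all(op <= 2 * xp + 1e-12))

  # single-stage loop oracle on a tiny input
  xt <- list(feature_map(array(rnorm(2 * 2 * 3), c(2, 2, 3, 1))))
  expect_equal(spatial_connectivity_attention(xt, st)[[1]],
               oracle_sca(st, xt)[[1]], tolerance = 1e-6)
})

test_that("shape preservation holds across randomized shapes", {
  set.seed(7)
  for (i in 1:5) {
    H <- sample(c(4, 6, 8), 1); W <- sample(c(4, 6, 8), 1)
    C <- 4 * sample(1:3, 1); B <- sample(1:2, 1)
    x <- array(rnorm(H * W * C * B), c(H, W, C, B))
    expect_identical(dim(dual_attention(x, da_state(C))), dim(x))
    out_c <- 4 * sample(1:3, 1)
    expect_identical(dim(refinement_dilated_conv(x, rdc_state(C, out_c))),
                     as.integer(c(H, W, out_c, B)))
    expect_identical(dim(spatial_connectivity_attention(list(x))[[1]]),
                     dim(x))
  }
})

test_that("every block parameter receives a defined, nonzero gradient", {
  set.seed(8)
  cases <- list(
    list(st = conv_block_state(4, 8, bias = TRUE),
         fw = function(s, x) weedseg:::conv_block_fw(s, x, training = TRUE),
         bw = weedseg:::conv_block_bw, dims = c(6, 6, 4, 2)),
    list(st = da_state(4), fw = weedseg:::da_fw, bw = weedseg:::da_bw,
         dims = c(4, 4, 4, 2)),
    list(st = rdc_state(8, 8), fw = weedseg:::rdc_fw, bw = weedseg:::rdc_bw,
         dims = c(5, 5, 8, 2)))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$dims)), cs$dims)
    r <- cs$fw(cs$st, x)
    res <- cs$bw(cs$st, r$cache, array(1, dim(r$y)))
    g <- weedseg:::flatten_grads(cs$st, res$grads)
    p <- weedseg:::collect_params(cs$st)
    expect_setequal(names(g), names(p))
    for (nm in names(g)) {
      expect_true(all(is.finite(g[[nm]])), info = nm)
      expect_true(any(g[[nm]] != 0), info = nm)
    }
  }
})
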