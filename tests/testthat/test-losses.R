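# The compound Dice + cross-entropy objective.

onehot_probs <- function(mask, K = 3) {
  d <- dim(mask)
  p <- array(0, c(d[1], d[2], K, d[3]))
  for (k in seq_len(K)) p[, , k, ] <- as.double(mask == k - 1L)
  p
}

test_that("Dice loss: endpoints and the hand-evaluated overlap case", {
  m <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  p <- onehot_probs(m)
  expect_equal(dice_loss(p, m), 0, tolerance = 1e-6)

  # single class, p = (1, 0) against g = (0.5, 0.5): 1 - 1/1.5 = 1/3
  expect_equal(1 - weedseg:::dice_coefficient(c(1, 0), c(0.5, 0.5)), 1 / 3)

  # disjoint one-hot masks: no overlap anywhere, loss 1 (up to smooth)
  truth <- array(0L, c(2, 2, 1))
  pred <- onehot_probs(array(1L, c(2, 2, 1)))
  d <- dice_loss(pred, truth)
  expect_equal(d, 1, tolerance = 1e-5)
  expect_true(d >= 0 && d <= 1)

  expect_error(dice_loss(pred, array(0L, c(3, 3, 1))), "disagree")
})

test_that("cross-entropy: closed forms", {
  m <- array(sample(0:2, 18, TRUE), c(3, 3, 2))
  expect_equal(cross_entropy_loss(onehot_probs(m), m), 0, tolerance = 1e-10)
  half <- array(0.5, c(3, 3, 3, 2))
  expect_equal(cross_entropy_loss(half, m), log(2), tolerance = 1e-12)
  unif <- array(1 / 3, c(3, 3, 3, 2))
  expect_equal(cross_entropy_loss(unif, m), log(3), tolerance = 1e-12)
})

test_that("compound loss is the stated affine combination", {
  # the worked arithmetic: 0.8 * (1/3) + 0.2 * ln 2
  expect_equal(0.8 * (1 / 3) + 0.2 * log(2), 0.4053, tolerance = 1e-4)

  set.seed(1)
  for (i in 1:5) {
    logits <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
    m <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
    probs <- weedseg:::softmax_classes(logits)
    w <- runif(2)
    cfg <- loss_config(dice_weight = w[1], ce_weight = w[2])
    expect_equal(compound_loss(logits, m, cfg),
                 w[1] * dice_loss(probs, m) +
                   w[2] * cross_entropy_loss(probs, m),
                 tolerance = 1e-12)
  }

  # weights (1, 0) reduce to the Dice loss exactly
  logits <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  m <- array(sample(0:2, 16, TRUE), c(4, 4, 1))
  expect_identical(compound_loss(logits, m, loss_config(1, 0)),
                   dice_loss(weedseg:::softmax_classes(logits), m))

  # near-perfect logits drive the compound loss to ~0
  big <- onehot_probs(m) * 50
  expect_lt(compound_loss(big, m), 1e-5)
})

test_that("loss gradients are finite and match numeric differentiation", {
  set.seed(2)
  logits <- array(runif(3 * 3 * 3 * 2, -10, 10), c(3, 3, 3, 2))
  m <- array(sample(0:2, 18, TRUE), c(3, 3, 2))
  g <- weedseg:::compound_loss_grad(logits, m)
  expect_true(all(is.finite(g$glogits)))
  expect_equal(g$loss, compound_loss(logits, m), tolerance = 1e-12)
  num <- numeric_gradient(function(v)
    compound_loss(array(v, dim(logits)), m), as.vector(logits))
  expect_equal(as.vector(g$glogits), num, tolerance = 1e-5)
})
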