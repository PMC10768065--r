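# Compound Dice + cross-entropy training objective.

#' Loss configuration
#'
#' @param dice_weight,ce_weight non-negative mixing weights; the defaults
#'   (0.8 Dice, 0.2 cross-entropy) sum to one.
#' @param smooth small constant added to the Dice denominator so absent
#'   classes do not divide by zero.
#' @return a `ws_loss_config` list.
#' @export
loss_config <- function(dice_weight = 0.8, ce_weight = 0.2, smooth = 1e-6) {
  if (dice_weight < 0 || ce_weight < 0)
    stop("loss_config: weights must be non-negative")
  structure(list(dice_weight = dice_weight, ce_weight = ce_weight,
                 smooth = smooth), class = "ws_loss_config")
}

# coerce a class mask to an H x W x B integer array and check labels
check_mask <- function(target, num_classes, what = "target") {
  if (is.null(dim(target))) stop(sprintf("`%s` must be an array", what))
  d <- dim(target)
  if (length(d) == 2) dim(target) <- c(d, 1L)
  if (length(dim(target)) != 3)
    stop(sprintf("`%s` must be an H x W x B class mask", what))
  target <- array(as.integer(target), dim(target))
  if (any(target < 0L) || any(target >= num_classes))
    stop(sprintf("`%s` has labels outside [0, %d)", what, num_classes))
  target
}

mask_onehot <- function(target, num_classes) {
  d <- dim(target)
  oh <- array(0, c(d[1], d[2], num_classes, d[3]))
  for (k in seq_len(num_classes))
    oh[, , k, ] <- as.double(target == k - 1L)
  oh
}

check_probs_target <- function(probs, target) {
  check_fmap(probs, "probs")
  d <- dim(probs)
  target <- check_mask(target, d[3])
  td <- dim(target)
  if (td[1] != d[1] || td[2] != d[2] || td[3] != d[4])
    stop("loss: `probs` and `target` shapes disagree")
  target
}

#' Soft Dice loss
#'
#' One minus twice the overlap between predicted class probabilities and the
#' one-hot target, divided by the sum of their squared masses. Computed per
#' class over all `B x H x W` pixels, then averaged over classes; `smooth`
#' is added to each denominator.
#'
#' @param probs class probabilities, `H x W x K x B` (non-negative, summing
#'   to ~1 per pixel).
#' @param target integer class mask `H x W x B` with labels in `[0, K)`.
#' @param smooth Dice smoothing constant.
#' @return a scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, smooth = 1e-6) {
  target <- check_probs_target(probs, target)
  K <- dim(probs)[3]
  mean(vapply(seq_len(K), function(k) {
    p <- probs[, , k, ]
    g <- as.double(target == k - 1L)
    1 - 2 * sum(p * g) / (sum(p * p) + sum(g * g) + smooth)
  }, numeric(1)))
}

# raw two-vector Dice coefficient of Eq-style hand checks
dice_coefficient <- function(p, g, smooth = 0) {
  2 * sum(p * g) / (sum(p * p) + sum(g * g) + smooth)
}

#' Cross-entropy loss
#'
#' Mean over pixels of the negative log predicted probability of the true
#' class; probabilities are clamped at 1e-12 before the log.
#'
#' @inheritParams dice_loss
#' @return a non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, target) {
  target <- check_probs_target(probs, target)
  d <- dim(probs)
  K <- d[3]
  tot <- 0
  for (k in seq_len(K)) {
    p <- probs[, , k, ]
    sel <- target == k - 1L
    tot <- tot - sum(log(pmax(p[sel], 1e-12)))
  }
  tot / prod(d[c(1, 2, 4)])
}

# stable softmax over the class axis of an H x W x K x B array
softmax_classes <- function(logits) {
  d <- dim(logits)
  m <- logits[, , 1, , drop = FALSE]
  if (d[3] > 1) for (k in 2:d[3]) m <- pmax(m, logits[, , k, , drop = FALSE])
  e <- exp(logits - array(m[, , rep(1, d[3]), , drop = FALSE], d))
  s <- e[, , 1, , drop = FALSE]
  if (d[3] > 1) for (k in 2:d[3]) s <- s + e[, , k, , drop = FALSE]
  e / array(s[, , rep(1, d[3]), , drop = FALSE], d)
}

#' Compound segmentation loss
#'
#' Applies a softmax over the class axis of the logits and returns
#' `dice_weight * Dice + ce_weight * cross-entropy` (defaults 0.8 / 0.2).
#'
#' @param logits unnormalized class scores, `H x W x K x B`.
#' @param target integer class mask `H x W x B`.
#' @param cfg a [loss_config()].
#' @return a scalar; zero only for a perfect prediction.
#' @export
compound_loss <- function(logits, target, cfg = loss_config()) {
  check_fmap(logits, "logits")
  probs <- softmax_classes(logits)
  cfg$dice_weight * dice_loss(probs, target, cfg$smooth) +
    cfg$ce_weight * cross_entropy_loss(probs, target)
}

# loss + gradient with respect to the logits (training path)
compound_loss_grad <- function(logits, target, cfg = loss_config()) {
  d <- dim(logits)
  K <- d[3]
  target <- check_probs_target(logits, target)
  probs <- softmax_classes(logits)
  npix <- prod(d[c(1, 2, 4)])
  gp <- array(0, d)
  dice_terms <- numeric(K)
  ce <- 0
  for (k in seq_len(K)) {
    p <- probs[, , k, , drop = FALSE]
    g <- array(as.double(target == k - 1L), dim(p))
    num <- 2 * sum(p * g)
    den <- sum(p * p) + sum(g * g) + cfg$smooth
    dice_terms[k] <- 1 - num / den
    # d(1 - num/den)/dp, averaged over K classes
    gdice <- -(2 * g * den - num * 2 * p) / den^2 / K
    pc <- pmax(p, 1e-12)
    ce <- ce - sum(log(pc[g > 0]))
    gce <- -g / pc / npix
    gp[, , k, ] <- cfg$dice_weight * gdice + cfg$ce_weight * gce
  }
  ce <- ce / npix
  dice <- mean(dice_terms)
  # softmax backward
  inner <- probs[, , 1, , drop = FALSE] * gp[, , 1, , drop = FALSE]
  if (K > 1) for (k in 2:K)
    inner <- inner + probs[, , k, , drop = FALSE] * gp[, , k, , drop = FALSE]
  glogits <- probs * (gp - array(inner[, , rep(1, K), , drop = FALSE], d))
  list(loss = cfg$dice_weight * dice + cfg$ce_weight * ce,
       dice = dice, ce = ce, glogits = glogits)
}
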