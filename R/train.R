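# Training loop: AdamW with decoupled weight decay, per-epoch cosine
# annealing of the learning rate, periodic checkpointing, and seeded
# reproducibility.

#' Training configuration
#'
#' Defaults follow the reference protocol: AdamW with learning rate 0.001,
#' weight decay 0.01, batch size 6, 150 epochs, cosine annealing to zero,
#' and a checkpoint every 5 epochs.
#'
#' @param lr initial learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs (also the cosine period).
#' @param checkpoint_every save a checkpoint every this many epochs; must
#'   not exceed `epochs`.
#' @param loss a [loss_config()].
#' @param seed integer seed controlling shuffling (and any other training
#'   randomness).
#' @param device compute device identifier; only `"cpu"` exists in this
#'   implementation.
#' @return a `ws_train_config` list.
#' @export
train_config <- function(lr = 0.001, weight_decay = 0.01, batch_size = 6,
                         epochs = 150, checkpoint_every = 5,
                         loss = loss_config(), seed = 1L, device = "cpu") {
  if (lr <= 0 || weight_decay < 0 || batch_size < 1 || epochs < 1 ||
      checkpoint_every < 1)
    stop("train_config: lr/batch_size/epochs/checkpoint_every must be ",
         "positive and weight_decay non-negative")
  if (checkpoint_every > epochs)
    stop("train_config: `checkpoint_every` must not exceed `epochs`")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 checkpoint_every = as.integer(checkpoint_every),
                 loss = loss, seed = as.integer(seed), device = device),
            class = "ws_train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = 0.5 * lr0 * (1 + cos(pi * e / epochs))`, evaluated once per
#' epoch, decaying from `lr0` at epoch 0 to 0 at the final epoch.
#'
#' @param epoch epoch index in `0:epochs`.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs)
    stop("cosine_lr: `epoch` must lie in [0, ", cfg$epochs, "]")
  max(0.5 * cfg$lr * (1 + cos(pi * epoch / cfg$epochs)), 0)
}

# one decoupled-weight-decay Adam update over flat parameter lists
adamw_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * wd * params[[nm]] -
      lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# stack a list of H x W x C images into an H x W x C x B batch
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(d, length(imgs)))
}

stack_masks <- function(masks) {
  d <- dim(masks[[1]])[1:2]
  array(as.integer(unlist(masks, use.names = FALSE)),
        c(d, length(masks)))
}

#' Train the network
#'
#' AdamW updates under the per-epoch cosine learning-rate schedule, with a
#' checkpoint every `checkpoint_every` epochs and at the end (plus a
#' best-validation-MIOU checkpoint when `val_data` is given). Runs are
#' reproducible on one device for a fixed seed.
#'
#' @param net a `weednet`.
#' @param data training pairs: list of `list(image =, mask =)`.
#' @param cfg a [train_config()].
#' @param val_data optional validation pairs evaluated each epoch.
#' @param checkpoint_dir optional directory for checkpoints; `NULL`
#'   disables saving.
#' @param max_steps optional cap on total optimizer steps (for smoke
#'   tests); training stops cleanly when reached.
#' @param target_miou optional early-stop threshold on training-set MIOU,
#'   checked at each epoch end when supplied.
#' @param verbose print a line per epoch?
#' @return `list(net =, history =)`; the history is a tibble with one row
#'   per epoch (`epoch`, `loss`, `lr`, and validation metrics if
#'   available), classed `ws_history` for `autoplot()`.
#' @export
train_network <- function(net, data, cfg = train_config(), val_data = NULL,
                          checkpoint_dir = NULL, max_steps = Inf,
                          target_miou = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "weednet"))
  if (!inherits(cfg, "ws_train_config"))
    stop("train_network: `cfg` must come from train_config()")
  if (!is.list(data) || length(data) == 0)
    stop("train_network: empty training dataset")
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  params <- collect_params(net)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  hist <- list()
  step <- 0
  best_miou <- -Inf
  n <- length(data)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_lr(epoch - 1, cfg)
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        if (step >= max_steps) break
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        x <- stack_images(lapply(data[idx], `[[`, "image"))
        y <- stack_masks(lapply(data[idx], `[[`, "mask"))
        fw <- net_fw(net, x, training = TRUE)
        net <- fw$net
        lg <- compound_loss_grad(fw$y, y, cfg$loss)
        bw <- net_bw(net, fw$caches, lg$glogits)
        grads <- flatten_grads(net, bw$grads)
        step <- step + 1
        upd <- adamw_step(collect_params(net), grads, state, lr,
                          cfg$weight_decay, step)
        state <- upd$state
        net <- set_params(net, upd$params)
        losses <- c(losses, lg$loss)
      }
      row <- tibble::tibble(epoch = epoch, loss = mean(losses), lr = lr,
                            steps = step)
      if (!is.null(val_data)) {
        rep <- evaluate_dataset(net, val_data)
        row$val_miou <- miou(rep)
        row$val_pixel_accuracy <- attr(rep, "pixel_accuracy")
        if (!is.null(checkpoint_dir) && row$val_miou > best_miou) {
          best_miou <- row$val_miou
          save_checkpoint(net, file.path(checkpoint_dir, "best.rds"),
                          extra = list(epoch = epoch, miou = best_miou))
        }
      }
      hist[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  lr %.6f", epoch, row$loss, lr))
      if (!is.null(checkpoint_dir) && epoch %% cfg$checkpoint_every == 0)
        save_checkpoint(net,
                        file.path(checkpoint_dir,
                                  sprintf("epoch_%03d.rds", epoch)),
                        extra = list(epoch = epoch))
      done <- FALSE
      if (!is.null(target_miou)) {
        rep <- evaluate_dataset(net, data)
        if (miou(rep) > target_miou) done <- TRUE
      }
      if (step >= max_steps || done) break
    }
  })
  if (!is.null(checkpoint_dir))
    save_checkpoint(net, file.path(checkpoint_dir, "last.rds"),
                    extra = list(epoch = length(hist)))
  history <- do.call(rbind, hist)
  class(history) <- c("ws_history", class(history))
  list(net = net, history = history)
}

#' Evaluate a saved checkpoint on a scene set
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param scenes list of `list(image =, mask =)` pairs.
#' @return a `ws_metrics_report`.
#' @export
evaluate_checkpoint <- function(path, scenes) {
  ck <- load_checkpoint(path)
  evaluate_dataset(ck$net, scenes)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.ws_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "Compound loss (0.8 Dice + 0.2 CE)") +
    ggplot2::theme_minimal()
  if ("val_miou" %in% names(df))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = val_miou),
                                colour = "#31a354", linetype = 2)
  p
}

#' @export
autoplot.ws_metrics_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = name, y = iou)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::geom_hline(yintercept = attr(object, "miou"), linetype = 2) +
    ggplot2::labs(x = NULL, y = "IOU",
                  subtitle = sprintf("MIOU = %.4f", attr(object, "miou"))) +
    ggplot2::theme_minimal()
}
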