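# Six-stage U-shaped encoder-decoder assembly and its ablation variants.

#' Architecture configuration
#'
#' Describes the six-stage U-shaped network: the per-stage channel plan,
#' which encoder stages carry the dual attention block (before max pooling)
#' and the refinement dilated conv block (instead of the Conv2d block), and
#' whether the skip connections are gated by spatial connectivity attention.
#'
#' @param stage_channels six positive integers; the default channel plan is
#'   `c(8, 16, 24, 32, 48, 64)`.
#' @param in_channels input image channels (3 for RGB).
#' @param num_classes output classes (3: background, crop, weed).
#' @param da_stages encoder stages (subset of 2:6) with a dual attention
#'   block ahead of the stage's max pooling.
#' @param rdc_stages encoder stages (subset of 2:6) whose Conv2d block is
#'   replaced by the refinement dilated conv block; default 4:6.
#' @param use_sca gate the skip connections with spatial connectivity
#'   attention?
#' @param input_size default spatial size `c(H, W)` used for profiling.
#' @return an `ws_arch_config` list.
#' @export
arch_config <- function(stage_channels = c(8, 16, 24, 32, 48, 64),
                        in_channels = 3, num_classes = 3,
                        da_stages = 2:6, rdc_stages = 4:6,
                        use_sca = TRUE, input_size = c(256, 256)) {
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != 6 || any(stage_channels < 1))
    stop("arch_config: `stage_channels` must be six positive integers")
  da_stages <- sort(unique(as.integer(da_stages)))
  rdc_stages <- sort(unique(as.integer(rdc_stages)))
  if (length(da_stages) && (min(da_stages) < 2 || max(da_stages) > 6))
    stop("arch_config: `da_stages` must lie in 2:6")
  if (length(rdc_stages) && (min(rdc_stages) < 2 || max(rdc_stages) > 6))
    stop("arch_config: `rdc_stages` must lie in 2:6")
  for (i in da_stages)
    if (stage_channels[i - 1] %% 4 != 0)
      stop("arch_config: dual attention at stage ", i, " needs incoming ",
           "channels divisible by 4 (got ", stage_channels[i - 1], ")")
  for (i in rdc_stages)
    if (stage_channels[i - 1] %% 4 != 0)
      stop("arch_config: RDC at stage ", i, " needs incoming channels ",
           "divisible by 4 (got ", stage_channels[i - 1], ")")
  structure(list(stage_channels = stage_channels,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 da_stages = da_stages, rdc_stages = rdc_stages,
                 use_sca = isTRUE(use_sca),
                 input_size = as.integer(input_size)),
            class = "ws_arch_config")
}

#' Build the segmentation network
#'
#' Encoder stage 1 is a Conv2d block at full resolution; each later stage
#' optionally applies dual attention at the incoming resolution, halves the
#' grid with 2x2 max pooling, and extracts features with a Conv2d block or
#' an RDC block. Decoder stages apply a (biased) Conv2d block at the coarse
#' resolution, upsample bilinearly by 2, and add the (optionally SCA-gated)
#' encoder output of the matching stage. A bare 3x3 convolution maps the
#' final 8-channel map to class logits.
#'
#' @param config an [arch_config()].
#' @return a `weednet` object.
#' @examples
#' set.seed(1)
#' net <- build_variant("U_VI")
#' count_parameters(net)
#' @export
build_network <- function(config = arch_config()) {
  if (!inherits(config, "ws_arch_config"))
    stop("build_network: `config` must come from arch_config()")
  ch <- config$stage_channels
  enc <- list(stage1 = conv_block_state(config$in_channels, ch[1]))
  for (i in 2:6) {
    st <- list()
    if (i %in% config$da_stages) st$da <- da_state(ch[i - 1])
    st$feat <- if (i %in% config$rdc_stages)
      rdc_state(ch[i - 1], ch[i])
    else
      conv_block_state(ch[i - 1], ch[i])
    enc[[paste0("stage", i)]] <- st
  }
  dec <- list()
  for (i in 6:2)
    dec[[paste0("d", i)]] <- conv_block_state(ch[i], ch[i - 1], bias = TRUE)
  structure(list(type = "network",
                 config = config,
                 enc = enc,
                 sca = if (config$use_sca) sca_state(),
                 dec = dec,
                 head = new_conv2d(3, 3, ch[1], config$num_classes,
                                   pad = 1, bias = TRUE)),
            class = "weednet")
}

#' Ablation variants of the network
#'
#' @param name one of `"U_VI"` (plain baseline), `"U_VI+RDC"`, `"U_VI+DA"`,
#'   `"U_VI+SCA"`, `"U_VI+RDC+DA"`, `"U_VI+RDC+DA+SCA"` or its alias
#'   `"full"`.
#' @param ... passed on to [arch_config()] (e.g. `num_classes`).
#' @return a `weednet` object.
#' @export
build_variant <- function(name, ...) {
  cfgs <- list(
    "U_VI"           = list(da = integer(), rdc = integer(), sca = FALSE),
    "U_VI+RDC"       = list(da = integer(), rdc = 4:6,       sca = FALSE),
    "U_VI+DA"        = list(da = 2:6,       rdc = integer(), sca = FALSE),
    "U_VI+SCA"       = list(da = integer(), rdc = integer(), sca = TRUE),
    "U_VI+RDC+DA"    = list(da = 2:6,       rdc = 4:6,       sca = FALSE),
    "U_VI+RDC+DA+SCA" = list(da = 2:6,      rdc = 4:6,       sca = TRUE)
  )
  key <- if (identical(name, "full")) "U_VI+RDC+DA+SCA" else name
  if (!key %in% names(cfgs))
    stop("build_variant: unknown variant '", name, "'; valid names: ",
         paste(c(names(cfgs), "full"), collapse = ", "))
  v <- cfgs[[key]]
  build_network(arch_config(da_stages = v$da, rdc_stages = v$rdc,
                            use_sca = v$sca, ...))
}

variant_names <- function() {
  c("U_VI", "U_VI+RDC", "U_VI+DA", "U_VI+SCA", "U_VI+RDC+DA",
    "U_VI+RDC+DA+SCA")
}

# --- forward / backward -----------------------------------------------------

net_fw <- function(net, x, training = FALSE) {
  check_fmap(x)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("forward: input height and width must be divisible by 32 ",
         "(five 2x2 poolings); got ", d[1], "x", d[2])
  if (d[3] != net$config$in_channels)
    stop("forward: expected ", net$config$in_channels, " input channels")
  E <- vector("list", 6)
  caches <- list(enc = vector("list", 6))
  s1 <- conv_block_fw(net$enc$stage1, x, training)
  if (training) net$enc$stage1 <- s1$layer
  E[[1]] <- s1$y
  caches$enc[[1]] <- s1$cache
  h <- s1$y
  for (i in 2:6) {
    st <- net$enc[[paste0("stage", i)]]
    cc <- list()
    if (!is.null(st$da)) {
      daf <- da_fw(st$da, h)
      cc$da <- daf$cache
      h <- daf$y
    }
    mp <- maxpool2_fw_(h)
    cc$pool <- list(idx = mp$idx, xdim = dim(h))
    h <- mp$y
    if (st$feat$type == "rdc") {
      ff <- rdc_fw(st$feat, h)
    } else {
      ff <- conv_block_fw(st$feat, h, training)
      if (training) {
        st$feat <- ff$layer
        net$enc[[paste0("stage", i)]] <- st
      }
    }
    cc$feat <- ff$cache
    h <- ff$y
    E[[i]] <- h
    caches$enc[[i]] <- cc
  }
  if (!is.null(net$sca)) {
    sf <- sca_fw(net$sca, E)
    G <- sf$y
    caches$sca <- sf$cache
  } else {
    G <- E
  }
  dcur <- G[[6]]
  caches$dec <- vector("list", 6)
  for (i in 6:2) {
    db <- conv_block_fw(net$dec[[paste0("d", i)]], dcur, training)
    if (training) net$dec[[paste0("d", i)]] <- db$layer
    up <- upsample2_fw_(db$y)
    dcur <- up + G[[i - 1]]
    caches$dec[[i]] <- db$cache
  }
  caches$head_x <- dcur
  logits <- conv2d_fw_(net$head, dcur)
  list(y = logits, caches = caches, net = net)
}

net_bw <- function(net, caches, glogits) {
  hb <- conv2d_bw_(net$head, caches$head_x, glogits)
  grads <- list(head = hb$grads, dec = list(), enc = list())
  gG <- vector("list", 6)
  gd <- hb$gx
  for (i in 2:6) {
    gG[[i - 1]] <- gd
    gup <- upsample2_bw_(gd)
    db <- conv_block_bw(net$dec[[paste0("d", i)]], caches$dec[[i]], gup)
    grads$dec[[paste0("d", i)]] <- db$grads
    gd <- db$gx
  }
  gG[[6]] <- gd
  if (!is.null(net$sca)) {
    sb <- sca_bw(net$sca, caches$sca, gG)
    grads$sca <- sb$grads
    gE <- sb$gx
  } else {
    gE <- gG
  }
  g <- gE[[6]]
  for (i in 6:2) {
    st <- net$enc[[paste0("stage", i)]]
    cc <- caches$enc[[i]]
    stg <- list()
    if (st$feat$type == "rdc") {
      fb <- rdc_bw(st$feat, cc$feat, g)
    } else {
      fb <- conv_block_bw(st$feat, cc$feat, g)
    }
    stg$feat <- fb$grads
    g <- maxpool2_bw_(cc$pool, fb$gx)
    if (!is.null(st$da)) {
      dab <- da_bw(st$da, cc$da, g)
      stg$da <- dab$grads
      g <- dab$gx
    }
    grads$enc[[paste0("stage", i)]] <- stg
    g <- g + gE[[i - 1]]
  }
  s1 <- conv_block_bw(net$enc$stage1, caches$enc[[1]], g)
  grads$enc$stage1 <- s1$grads
  list(gx = s1$gx, grads = grads)
}

#' Run the network forward
#'
#' @param net a `weednet` from [build_network()] or [build_variant()].
#' @param images feature map `H x W x C x B` with `H`, `W` divisible by 32.
#' @return class logits of shape `H x W x num_classes x B` (no softmax;
#'   class probabilities are formed only at inference/metric time).
#' @export
forward <- function(net, images) {
  stopifnot(inherits(net, "weednet"))
  net_fw(net, feature_map(images), training = FALSE)$y
}

#' Predict class masks for a batch of images
#'
#' @param object a `weednet`.
#' @param images feature map `H x W x C x B` (or `H x W x C` for one image).
#' @param ... unused.
#' @return an `H x W x B` integer array of class labels (0 = background,
#'   1 = crop, 2 = weed under the default three-class head).
#' @export
predict.weednet <- function(object, images, ...) {
  logits <- forward(object, images)
  logits_to_mask(logits)
}

# argmax over the class axis; ties resolved to the lowest class index
logits_to_mask <- function(logits) {
  d <- dim(logits)
  K <- d[3]
  best <- logits[, , 1, , drop = FALSE]
  lab <- array(0L, c(d[1], d[2], 1, d[4]))
  if (K > 1) for (k in 2:K) {
    lk <- logits[, , k, , drop = FALSE]
    upd <- lk > best
    best[upd] <- lk[upd]
    lab[upd] <- k - 1L
  }
  array(lab, c(d[1], d[2], d[4]))
}

#' @export
print.weednet <- function(x, ...) {
  cfg <- x$config
  cat("<weednet> six-stage U-shaped encoder-decoder\n")
  cat("  channels:", paste(cfg$stage_channels, collapse = "-"), "\n")
  cat("  DA stages:", if (length(cfg$da_stages)) paste(cfg$da_stages,
      collapse = ",") else "none",
      "| RDC stages:", if (length(cfg$rdc_stages)) paste(cfg$rdc_stages,
      collapse = ",") else "none",
      "| SCA:", if (cfg$use_sca) "on" else "off", "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}

# --- parameter walking ------------------------------------------------------

# Flatten every learnable array in a module tree into a named list keyed by
# path (e.g. "enc/stage2/da/par/mem_k").
collect_params <- function(obj, path = character()) {
  out <- list()
  if (!is.list(obj)) return(out)
  if (!is.null(obj$par) && is.list(obj$par)) {
    for (nm in names(obj$par))
      out[[paste(c(path, "par", nm), collapse = "/")]] <- obj$par[[nm]]
  }
  for (nm in names(obj)) {
    if (identical(nm, "par")) next
    el <- obj[[nm]]
    if (is.list(el)) out <- c(out, collect_params(el, c(path, nm)))
  }
  out
}

# Flatten a gradient tree (child subtrees named like the module's children,
# own-parameter gradients named like the entries of `par`).
flatten_grads <- function(mod, gr, path = character()) {
  out <- list()
  pnames <- names(mod$par)
  for (nm in names(gr)) {
    if (nm %in% pnames) {
      out[[paste(c(path, "par", nm), collapse = "/")]] <- gr[[nm]]
    } else if (is.list(mod[[nm]])) {
      out <- c(out, flatten_grads(mod[[nm]], gr[[nm]], c(path, nm)))
    }
  }
  out
}

path_assign <- function(obj, parts, value) {
  if (length(parts) == 1) {
    obj[[parts]] <- value
    return(obj)
  }
  obj[[parts[1]]] <- path_assign(obj[[parts[1]]], parts[-1], value)
  obj
}

set_params <- function(net, flat) {
  for (p in names(flat))
    net <- path_assign(net, strsplit(p, "/", fixed = TRUE)[[1]], flat[[p]])
  net
}

# batch-norm running statistics (buffers, not trainable parameters)
collect_buffers <- function(obj, path = character()) {
  out <- list()
  if (!is.list(obj)) return(out)
  if (identical(obj$type, "bn")) {
    out[[paste(c(path, "run_mean"), collapse = "/")]] <- obj$run_mean
    out[[paste(c(path, "run_var"), collapse = "/")]] <- obj$run_var
    return(out)
  }
  for (nm in names(obj)) {
    el <- obj[[nm]]
    if (is.list(el)) out <- c(out, collect_buffers(el, c(path, nm)))
  }
  out
}

#' Count trainable scalars
#'
#' Sums the element counts of every learnable array in a network or block
#' (batch-norm running statistics are buffers and are not counted).
#'
#' @param net a `weednet` or any block state.
#' @return integer scalar count.
#' @examples
#' count_parameters(sca_state()) # 2*7*7 + 1 = 99
#' @export
count_parameters <- function(net) {
  sum(vapply(collect_params(net), length, numeric(1)))
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a network checkpoint
#'
#' A checkpoint stores the architecture configuration, every learnable
#' array and the batch-norm running statistics; loading rebuilds the network
#' and restores them exactly (bit-identical forward passes).
#'
#' @param net a `weednet`.
#' @param path file path.
#' @param extra optional list stored alongside (e.g. optimizer state).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with elements `net` and `extra`.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "weednet"))
  saveRDS(list(config = net$config,
               params = collect_params(net),
               buffers = collect_buffers(net),
               extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("load_checkpoint: cannot read checkpoint: ", conditionMessage(e)))
  if (!is.list(ck) || !all(c("config", "params", "buffers") %in% names(ck)))
    stop("load_checkpoint: file is not a weedseg checkpoint")
  net <- build_network(ck$config)
  net <- set_params(net, ck$params)
  for (p in names(ck$buffers))
    net <- path_assign(net, strsplit(p, "/", fixed = TRUE)[[1]],
                       ck$buffers[[p]])
  list(net = net, extra = ck$extra)
}
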