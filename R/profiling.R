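# Analytic complexity profiling: exact trainable-parameter counts and
# multiply-accumulate (MAC) counts at a stated input size.
#
# FLOP convention (calibrated against the reference complexity tables,
# matching the common PyTorch profilers): 1 FLOP = 1 MAC; a convolution
# costs out_elems * k^2 * Cin / groups plus one op per output element if it
# carries a bias; a matrix product N x a times a x b costs N*a*b (any bias
# is free); batch normalization costs 2 ops per element; global average
# pooling 1 op per input element; parameter-free group normalization,
# activations, softmax, max pooling, bilinear interpolation and elementwise
# products are free.

conv_macs <- function(hw, k2, cin, cout, groups = 1, bias = FALSE) {
  hw * (k2 * (cin / groups) * cout + if (bias) cout else 0)
}

# per-module (params, macs) rows for a network at the given input size
.profile_rows <- function(net, input_size) {
  cfg <- net$config
  ch <- cfg$stage_channels
  H <- input_size[1]; W <- input_size[2]
  rows <- list()
  add <- function(module, params, macs)
    rows[[length(rows) + 1]] <<- tibble::tibble(module = module,
                                                params = params, macs = macs)
  hw <- H * W
  # encoder stage 1: conv block at full resolution
  add("enc/stage1 conv", 9 * cfg$in_channels * ch[1] + 2 * ch[1],
      conv_macs(hw, 9, cfg$in_channels, ch[1]) + 2 * ch[1] * hw)
  hwi <- hw
  for (i in 2:6) {
    cin <- ch[i - 1]; cout <- ch[i]
    if (i %in% cfg$da_stages) {
      # DA runs before pooling, at the incoming resolution
      da_p <- 10 * cin^2 + cin + 3
      da_m <- 2 * conv_macs(hwi, 1, cin, cin) +      # two 1x1 projections
        2 * (hwi * cin * 4 * cin) +                  # memory matmuls
        cin * hwi +                                  # global average pool
        3 * cin                                      # channel 1-D conv
      add(sprintf("enc/stage%d DA", i), da_p, da_m)
    }
    hwi <- hwi / 4 # 2x2 max pooling
    if (i %in% cfg$rdc_stages) {
      p <- 9 * cin + cin + cin * cout # depthwise branches + bias + 1x1 fuse
      m <- conv_macs(hwi, 9, cin, cin, groups = cin, bias = TRUE) +
        conv_macs(hwi, 1, cin, cout)
      add(sprintf("enc/stage%d RDC", i), p, m)
    } else {
      add(sprintf("enc/stage%d conv", i), 9 * cin * cout + 2 * cout,
          conv_macs(hwi, 9, cin, cout) + 2 * cout * hwi)
    }
  }
  if (cfg$use_sca) {
    # shared 7x7 gate at each encoder output resolution
    res <- hw / 4^(0:5)
    add("sca shared conv", 2 * 49 + 1,
        sum(conv_macs(res, 49, 2, 1, bias = TRUE)))
  }
  # decoder: conv block at the coarse resolution, then upsample
  for (i in 6:2) {
    hwd <- hw / 4^(i - 1)
    add(sprintf("dec/d%d conv", i),
        9 * ch[i] * ch[i - 1] + ch[i - 1] + 2 * ch[i - 1],
        conv_macs(hwd, 9, ch[i], ch[i - 1], bias = TRUE) +
          2 * ch[i - 1] * hwd)
  }
  add("head conv", 9 * ch[1] * cfg$num_classes + cfg$num_classes,
      conv_macs(hw, 9, ch[1], cfg$num_classes, bias = TRUE))
  do.call(rbind, rows)
}

#' Count multiply-accumulate operations of one forward pass
#'
#' Analytic MAC count for a single image at the given input size, under the
#' package's calibrated profiler convention (see the vignette): convolution
#' and matrix-product MACs plus conv-bias and batch-norm elementwise ops;
#' activations, pooling, interpolation and parameter-free normalization are
#' excluded.
#'
#' @param net a `weednet`.
#' @param input_size spatial size `c(H, W)`, divisible by 32; defaults to
#'   the configured profiling size (256 x 256).
#' @return MAC count (numeric scalar).
#' @examples
#' set.seed(1)
#' count_flops(build_variant("U_VI")) / 1e9 # 0.1219 G
#' @export
count_flops <- function(net, input_size = NULL) {
  stopifnot(inherits(net, "weednet"))
  if (is.null(input_size)) input_size <- net$config$input_size
  if (any(input_size %% 32 != 0))
    stop("count_flops: input size must be divisible by 32")
  sum(.profile_rows(net, input_size)$macs)
}

#' Per-module complexity report
#'
#' @param net a `weednet` or a variant name accepted by [build_variant()].
#' @param input_size spatial size `c(H, W)`; defaults to the configured
#'   profiling size.
#' @return a `ws_complexity` tibble with one row per module plus a total
#'   row; columns `module`, `params`, `macs`, and scaled `params_M`,
#'   `flops_G`.
#' @export
complexity_report <- function(net, input_size = NULL) {
  if (is.character(net)) net <- build_variant(net)
  stopifnot(inherits(net, "weednet"))
  if (is.null(input_size)) input_size <- net$config$input_size
  rows <- .profile_rows(net, input_size)
  total <- tibble::tibble(module = "total", params = sum(rows$params),
                          macs = sum(rows$macs))
  out <- rbind(rows, total)
  out$params_M <- out$params / 1e6
  out$flops_G <- out$macs / 1e9
  # the analytic per-module parameter sum must agree with enumeration
  stopifnot(total$params == count_parameters(net))
  class(out) <- c("ws_complexity", class(out))
  attr(out, "input_size") <- input_size
  out
}

#' @export
print.ws_complexity <- function(x, ...) {
  sz <- attr(x, "input_size")
  cat(sprintf("Complexity at 1 x %d x %d x 3 input\n", sz[1], sz[2]))
  df <- data.frame(module = x$module,
                   params = x$params,
                   macs = format(x$macs, big.mark = ","))
  print(df, row.names = FALSE)
  tot <- x[x$module == "total", ]
  cat(sprintf("total: %.4f M params, %.4f G FLOPs (MACs)\n",
              tot$params_M, tot$flops_G))
  invisible(x)
}
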