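# Per-class one-vs-rest confusion counting and the evaluation metric suite
# (IOU, MIOU, precision, recall, F1) computed from aggregated pixel counts.

default_class_names <- c("background", "crop", "weed")

#' Per-class confusion counts
#'
#' One-vs-rest true/false positive/negative pixel counts for each class.
#' Counts are additive over images: sum the counts of an image set before
#' computing metrics (the convention behind dataset-level tables).
#'
#' @param pred,truth integer class masks (`H x W` or `H x W x B`) with
#'   labels in `[0, num_classes)`.
#' @param num_classes number of classes (3 by default).
#' @return a tibble of class `ws_confusion` with columns `class`, `tp`,
#'   `fp`, `fn`, `tn`; one row per class, counts in pixels.
#' @examples
#' p <- matrix(c(1L, 0L, 1L, 0L), 2)
#' t <- matrix(c(1L, 0L, 0L, 2L), 2)
#' confusion_counts(p, t, 3)
#' @export
confusion_counts <- function(pred, truth, num_classes = 3) {
  if (is.null(dim(pred))) pred <- as.matrix(pred)
  if (is.null(dim(truth))) truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("confusion_counts: `pred` and `truth` shapes differ")
  m <- .confusion_fw(as.integer(pred), as.integer(truth),
                     as.integer(num_classes))
  new_confusion(m, num_classes)
}

new_confusion <- function(m, num_classes) {
  cls <- seq_len(num_classes) - 1L
  nm <- if (num_classes == 3) default_class_names else paste0("class", cls)
  out <- tibble::tibble(class = cls, name = nm,
                        tp = m[, 1], fp = m[, 2], fn = m[, 3], tn = m[, 4])
  class(out) <- c("ws_confusion", class(out))
  out
}

#' Manually assemble confusion counts
#'
#' Useful for computing metrics from published per-class counts.
#'
#' @param tp,fp,fn,tn numeric vectors, one entry per class.
#' @return a `ws_confusion` tibble.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  k <- length(tp)
  stopifnot(length(fp) == k, length(fn) == k, length(tn) == k)
  new_confusion(cbind(tp, fp, fn, tn), k)
}

#' Sum confusion counts over images
#'
#' @param ... `ws_confusion` objects (or a single list of them).
#' @return their element-wise sum, a `ws_confusion` tibble.
#' @export
sum_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "ws_confusion")) xs <- xs[[1]]
  out <- xs[[1]]
  for (x in xs[-1]) {
    stopifnot(identical(x$class, out$class))
    out$tp <- out$tp + x$tp
    out$fp <- out$fp + x$fp
    out$fn <- out$fn + x$fn
    out$tn <- out$tn + x$tn
  }
  out
}

.counts_row <- function(counts, cls) {
  i <- match(cls, counts$class)
  if (is.na(i)) stop("unknown class label ", cls)
  counts[i, ]
}

# Zero-denominator conventions: a class that is absent and never predicted
# (tp+fp+fn = 0) scores 1 on every metric; otherwise a metric whose own
# denominator is zero scores 0.
.ratio <- function(num, den, empty) {
  if (empty) return(1)
  if (den == 0) return(0)
  num / den
}

#' Per-class metrics from confusion counts
#'
#' `precision` = TP/(TP+FP), `recall` = TP/(TP+FN),
#' `f1score` = 2PR/(P+R), `iou` = TP/(TP+FP+FN). A class absent from both
#' prediction and truth scores 1 by convention; any other zero denominator
#' scores 0.
#'
#' @param counts a `ws_confusion`.
#' @param cls class label (0-based integer as stored in `counts$class`).
#' @return a scalar in `[0, 1]`.
#' @export
precision <- function(counts, cls) {
  r <- .counts_row(counts, cls)
  .ratio(r$tp, r$tp + r$fp, r$tp + r$fp + r$fn == 0)
}

#' @rdname precision
#' @export
recall <- function(counts, cls) {
  r <- .counts_row(counts, cls)
  .ratio(r$tp, r$tp + r$fn, r$tp + r$fp + r$fn == 0)
}

#' @rdname precision
#' @export
f1score <- function(counts, cls) {
  p <- precision(counts, cls)
  r <- recall(counts, cls)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname precision
#' @export
iou <- function(counts, cls) {
  r <- .counts_row(counts, cls)
  .ratio(r$tp, r$tp + r$fp + r$fn, r$tp + r$fp + r$fn == 0)
}

#' Convert an F1 score to an IOU
#'
#' Uses the exact one-vs-rest identity `IOU = F1 / (2 - F1)`.
#'
#' @param f1 F1 score(s) in `[0, 1]`.
#' @return IOU value(s) in `[0, 1]`.
#' @export
f1_to_iou <- function(f1) {
  if (any(f1 < 0 | f1 > 1)) stop("f1_to_iou: `f1` must lie in [0, 1]")
  f1 / (2 - f1)
}

#' Metrics report from confusion counts
#'
#' @param counts a `ws_confusion` (aggregated over the image set).
#' @return a `ws_metrics_report`: a tibble with one row per class
#'   (`iou`, `precision`, `recall`, `f1`) carrying the mean IOU and pixel
#'   accuracy as attributes (see [miou()] and `glance()`).
#' @export
metrics_report <- function(counts) {
  stopifnot(inherits(counts, "ws_confusion"))
  out <- counts
  out$iou <- vapply(out$class, function(c) iou(counts, c), numeric(1))
  out$precision <- vapply(out$class, function(c) precision(counts, c),
                          numeric(1))
  out$recall <- vapply(out$class, function(c) recall(counts, c), numeric(1))
  out$f1 <- vapply(out$class, function(c) f1score(counts, c), numeric(1))
  attr(out, "miou") <- mean(out$iou)
  tot <- out$tp[1] + out$fp[1] + out$fn[1] + out$tn[1]
  attr(out, "pixel_accuracy") <- sum(out$tp) / tot
  class(out) <- c("ws_metrics_report", class(out))
  out
}

#' Mean IOU of a metrics report
#'
#' @param report a `ws_metrics_report`.
#' @return mean of the per-class IOU values.
#' @export
miou <- function(report) {
  stopifnot(inherits(report, "ws_metrics_report"))
  attr(report, "miou")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ws_metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("class", "name", "iou", "precision",
                                 "recall", "f1", "tp", "fp", "fn", "tn")])
}

#' @export
glance.ws_metrics_report <- function(x, ...) {
  tibble::tibble(miou = attr(x, "miou"),
                 pixel_accuracy = attr(x, "pixel_accuracy"),
                 classes = nrow(x),
                 pixels = x$tp[1] + x$fp[1] + x$fn[1] + x$tn[1])
}

#' @export
print.ws_metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", nrow(x), " classes, ",
      format(x$tp[1] + x$fp[1] + x$fn[1] + x$tn[1], big.mark = ","),
      " pixels)\n", sep = "")
  df <- data.frame(class = x$name,
                   IOU = round(x$iou, 4), Precision = round(x$precision, 4),
                   Recall = round(x$recall, 4), F1 = round(x$f1, 4))
  print(df, row.names = FALSE)
  cat("MIOU:", round(attr(x, "miou"), 4), "\n")
  invisible(x)
}

# nearest-neighbour resize of an integer label grid
resize_mask_nearest <- function(mask, size) {
  d <- dim(mask)
  if (length(d) == 2) dim(mask) <- c(d, 1L)
  d <- dim(mask)
  H <- size[1]; W <- size[2]
  ri <- pmin(pmax(floor((seq_len(H) - 0.5) * d[1] / H) + 1, 1), d[1])
  ci <- pmin(pmax(floor((seq_len(W) - 0.5) * d[2] / W) + 1, 1), d[2])
  out <- mask[ri, ci, , drop = FALSE]
  out
}

#' Evaluate a network on aligned image/mask pairs
#'
#' Runs the network in inference mode on each pair, takes the per-pixel
#' argmax over class logits, aggregates one-vs-rest confusion counts over
#' the whole set and builds a [metrics_report()]. Metrics are computed at
#' each mask's native resolution: predictions made at the network input
#' size are upsampled to the mask size with nearest-neighbour interpolation
#' first.
#'
#' @param net a `weednet`.
#' @param scenes list of `list(image =, mask =)` pairs; images are
#'   `H x W x C` arrays (values in any consistent scale the network was
#'   trained on), masks are integer `H x W` grids.
#' @return a `ws_metrics_report`.
#' @export
evaluate_dataset <- function(net, scenes) {
  if (!is.list(scenes) || length(scenes) == 0)
    stop("evaluate_dataset: `scenes` must be a non-empty list of pairs")
  K <- net$config$num_classes
  total <- NULL
  for (sc in scenes) {
    pred <- predict(net, feature_map(sc$image))
    mask <- sc$mask
    md <- dim(mask)[1:2]
    if (!identical(as.integer(dim(pred)[1:2]), as.integer(md)))
      pred <- resize_mask_nearest(array(pred, dim(pred)), md)
    cc <- confusion_counts(array(pred, md), array(mask, md), K)
    total <- if (is.null(total)) cc else sum_confusion(total, cc)
  }
  metrics_report(total)
}
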