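# Image / colour-mask IO, the label-palette codec, preprocessing and
# augmentation.
#
# Masks use the three-colour palette of the task: black = soil/paddy
# background (label 0), green = crop (label 1), red = weed (label 2).

ws_palette <- function() {
  rbind(background = c(0, 0, 0),
        crop       = c(0, 1, 0),
        weed       = c(1, 0, 0))
}

#' Decode a colour mask into class labels
#'
#' Black maps to 0 (soil/paddy background), green to 1 (crop), red to 2
#' (weed). Off-palette pixels (e.g. antialiasing artifacts) are assigned to
#' the nearest palette colour in RGB distance.
#'
#' @param rgb_mask `H x W x 3` array; values either in `[0, 1]` or 0-255.
#' @return an integer `H x W` class mask with values in `{0, 1, 2}`.
#' @examples
#' m <- array(0, c(2, 2, 3)); m[1, 1, 1] <- 1 # one red pixel
#' decode_color_mask(m)
#' @export
decode_color_mask <- function(rgb_mask) {
  d <- dim(rgb_mask)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("decode_color_mask: `rgb_mask` must be an H x W x 3 array")
  x <- rgb_mask
  if (max(x) > 1) x <- x / 255
  pal <- ws_palette()
  n <- d[1] * d[2]
  xm <- matrix(x, n, 3)
  # squared distance to each palette colour
  dist <- matrix(0, n, nrow(pal))
  for (k in seq_len(nrow(pal)))
    dist[, k] <- (xm[, 1] - pal[k, 1])^2 + (xm[, 2] - pal[k, 2])^2 +
      (xm[, 3] - pal[k, 3])^2
  lab <- max.col(-dist, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Encode class labels as a colour mask
#'
#' The inverse of [decode_color_mask()] on palette values.
#'
#' @param mask integer `H x W` class mask with values in `{0, 1, 2}`.
#' @return an `H x W x 3` array with values in `[0, 1]`.
#' @export
encode_color_mask <- function(mask) {
  if (is.null(dim(mask))) stop("encode_color_mask: `mask` must be a matrix")
  mask <- as.matrix(mask)
  if (any(mask < 0L | mask > 2L))
    stop("encode_color_mask: labels must lie in {0, 1, 2}")
  pal <- ws_palette()
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], 3))
  for (k in 0:2) {
    sel <- mask == k
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- pal[k + 1, ch]
      out[, , ch] <- pl
    }
  }
  out
}

# --- file IO -----------------------------------------------------------------

#' Read / write images and colour masks
#'
#' `read_image` loads a PNG or JPEG as an `H x W x 3` array in `[0, 1]`
#' (grayscale images are replicated over channels, alpha is dropped).
#' `write_image` writes PNG. `read_mask`/`write_mask` combine image IO with
#' the palette codec.
#'
#' @param path file path (`.png`, `.jpg`/`.jpeg`).
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask integer `H x W` class mask.
#' @return `read_image`: an array; `read_mask`: an integer mask; writers
#'   return `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("read_image: unsupported extension '", ext, "'"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) decode_color_mask(read_image(path))

#' @rdname read_image
#' @export
write_mask <- function(mask, path) {
  png::writePNG(encode_color_mask(mask), path)
  invisible(path)
}

#' Write / read a dataset directory
#'
#' The on-disk layout is `dir/images/<stem>.png` plus `dir/masks/<stem>.png`
#' with matching stems, so trainers are agnostic to whether a dataset is
#' real or synthetic.
#'
#' @param pairs list of `list(image =, mask =)` pairs.
#' @param dir dataset directory.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a list of
#'   pairs.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    stem <- sprintf("scene_%04d.png", i)
    write_image(pairs[[i]]$image, file.path(dir, "images", stem))
    write_mask(pairs[[i]]$mask, file.path(dir, "masks", stem))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (length(imgs) == 0) stop("read_dataset: no images under ", dir)
  lapply(imgs, function(p) {
    mp <- file.path(dir, "masks", basename(p))
    if (!file.exists(mp)) stop("read_dataset: missing mask for ", basename(p))
    list(image = read_image(p), mask = read_mask(mp))
  })
}

# --- resizing ----------------------------------------------------------------

# 1-D half-pixel-centre bilinear interpolation matrix (nout x nin)
.bilin_mat <- function(nout, nin) {
  s <- (seq_len(nout) - 0.5) * nin / nout - 0.5
  i0 <- pmin(pmax(floor(s), 0), nin - 1)
  i1 <- pmin(i0 + 1, nin - 1)
  t <- pmin(pmax(s - floor(s), 0), 1)
  m <- matrix(0, nout, nin)
  m[cbind(seq_len(nout), i0 + 1)] <- m[cbind(seq_len(nout), i0 + 1)] + 1 - t
  m[cbind(seq_len(nout), i1 + 1)] <- m[cbind(seq_len(nout), i1 + 1)] + t
  m
}

#' Resize an image bilinearly
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param size target `c(H, W)`.
#' @return resized array of the same rank.
#' @export
resize_bilinear <- function(image, size) {
  d <- dim(image)
  two_d <- length(d) == 2
  if (two_d) dim(image) <- c(d, 1L)
  d <- dim(image)
  A <- .bilin_mat(size[1], d[1])
  Bt <- t(.bilin_mat(size[2], d[2]))
  out <- array(0, c(size[1], size[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% image[, , c] %*% Bt
  if (two_d) dim(out) <- size
  out
}

#' Resize a class mask with nearest-neighbour sampling
#'
#' Labels are preserved exactly; no interpolation artifacts.
#'
#' @param mask integer `H x W` class mask.
#' @param size target `c(H, W)`.
#' @return resized integer mask.
#' @export
resize_nearest <- function(mask, size) {
  out <- resize_mask_nearest(as.matrix(mask), size)
  matrix(out, size[1], size[2])
}

# --- preprocessing -----------------------------------------------------------

#' Per-channel normalization statistics of a training split
#'
#' @param pairs list of `list(image =, mask =)` pairs.
#' @return list with numeric `mean` and `sd` of length 3.
#' @export
compute_norm_stats <- function(pairs) {
  n <- 0; s <- c(0, 0, 0); s2 <- c(0, 0, 0)
  for (p in pairs) {
    img <- p$image
    npx <- prod(dim(img)[1:2])
    for (c in 1:3) {
      s[c] <- s[c] + sum(img[, , c])
      s2[c] <- s2[c] + sum(img[, , c]^2)
    }
    n <- n + npx
  }
  m <- s / n
  list(mean = m, sd = sqrt(pmax(s2 / n - m^2, 1e-12)))
}

#' Standardize and resize an image/mask pair
#'
#' The image is resized bilinearly to `size` and standardized per channel;
#' the mask is resized with nearest-neighbour sampling so labels survive
#' unchanged.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask optional integer `H x W` class mask aligned with `image`.
#' @param size target spatial size, default `c(256, 256)`.
#' @param stats optional `list(mean =, sd =)` per-channel statistics from
#'   [compute_norm_stats()]; the fallback is mean 0.5, sd 0.5.
#' @return `list(image =, mask =)` with the standardized image.
#' @export
preprocess <- function(image, mask = NULL, size = c(256, 256), stats = NULL) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("preprocess: `image` must be H x W x 3")
  if (!is.null(mask) && !identical(as.integer(dim(mask)[1:2]),
                                   as.integer(d[1:2])))
    stop("preprocess: `image` and `mask` sizes disagree")
  if (is.null(stats)) stats <- list(mean = rep(0.5, 3), sd = rep(0.5, 3))
  img <- resize_bilinear(image, size)
  for (c in 1:3) img[, , c] <- (img[, , c] - stats$mean[c]) / stats$sd[c]
  list(image = img,
       mask = if (!is.null(mask)) resize_nearest(mask, size))
}

# --- augmentation ------------------------------------------------------------

flip_h <- function(x) {
  d <- dim(x)
  if (length(d) == 2) x[, d[2]:1] else x[, d[2]:1, , drop = FALSE]
}

flip_v <- function(x) {
  d <- dim(x)
  if (length(d) == 2) x[d[1]:1, ] else x[d[1]:1, , , drop = FALSE]
}

#' Gaussian blur of an image (labels untouched)
#'
#' Separable kernel with radius `ceiling(3 * sigma)`, replicate padding.
#'
#' @param image `H x W` or `H x W x C` array.
#' @param sigma blur standard deviation in pixels.
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    # rows, replicate padding
    H <- nrow(m)
    pad <- m[c(rep(1, r), seq_len(H), rep(H, r)), , drop = FALSE]
    out <- 0
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + H - 1), ,
                                                    drop = FALSE]
    out
  }
  d <- dim(image)
  two_d <- length(d) == 2
  if (two_d) dim(image) <- c(d, 1L)
  out <- image
  for (c in seq_len(dim(image)[3]))
    out[, , c] <- t(blur1(t(blur1(image[, , c]))))
  if (two_d) dim(out) <- d
  out
}

#' Randomly augment an aligned image/mask pair
#'
#' Horizontal and vertical flips (each with probability 1/2) are applied
#' jointly to image and mask; a random Gaussian blur (probability
#' `blur_prob`, sigma uniform in `sigma_range`) touches the image only.
#' Fully deterministic under `seed`.
#'
#' @param image `H x W x 3` array.
#' @param mask integer `H x W` class mask aligned with `image`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param flip apply random flips?
#' @param blur_prob probability of the Gaussian blur.
#' @param sigma_range range the blur sigma is drawn from.
#' @return `list(image =, mask =)`.
#' @export
augment <- function(image, mask, seed = NULL, flip = TRUE, blur_prob = 0.5,
                    sigma_range = c(0.1, 2)) {
  run <- function() {
    if (flip && runif(1) < 0.5) {
      image <<- flip_h(image)
      mask <<- flip_h(mask)
    }
    if (flip && runif(1) < 0.5) {
      image <<- flip_v(image)
      mask <<- flip_v(mask)
    }
    if (runif(1) < blur_prob)
      image <<- gaussian_blur(image, runif(1, sigma_range[1], sigma_range[2]))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  list(image = image, mask = mask)
}

#' Optional offline dataset-expansion transforms
#'
#' Shear ("miscut") and coarse elastic distortion, applied jointly to image
#' (bilinear) and mask (nearest). These mimic the offline expansion some
#' field datasets use; they are not part of the training-time augmentation
#' path.
#'
#' @param image `H x W x 3` array.
#' @param mask integer `H x W` class mask.
#' @param shear horizontal shear factor (columns shift by `shear * row`).
#' @param alpha,sigma elastic displacement amplitude (pixels) and smoothing.
#' @param seed integer seed for the elastic displacement field.
#' @return `list(image =, mask =)`.
#' @export
miscut_transform <- function(image, mask, shear = 0.1) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  src_c <- cols - shear * (rows - H / 2)
  .warp_pair(image, mask, rows, src_c)
}

#' @rdname miscut_transform
#' @export
elastic_transform <- function(image, mask, alpha = 6, sigma = 8, seed = 1) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  disp <- with_seed(seed, list(
    dr = gaussian_blur(matrix(runif(H * W, -1, 1), H, W), sigma),
    dc = gaussian_blur(matrix(runif(H * W, -1, 1), H, W), sigma)))
  norm <- function(m) m / max(abs(m), 1e-9) * alpha
  rows <- matrix(seq_len(H), H, W) + norm(disp$dr)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) + norm(disp$dc)
  .warp_pair(image, mask, rows, cols)
}

# sample image (bilinear) and mask (nearest) at fractional source coords
.warp_pair <- function(image, mask, src_r, src_c) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  r0 <- pmin(pmax(floor(src_r), 1), H)
  r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(src_c), 1), W)
  c1 <- pmin(c0 + 1, W)
  tr <- pmin(pmax(src_r - r0, 0), 1)
  tc <- pmin(pmax(src_c - c0, 0), 1)
  out <- image
  for (ch in seq_len(d[3])) {
    pl <- image[, , ch]
    out[, , ch] <-
      pl[cbind(c(r0), c(c0))] * (1 - tr) * (1 - tc) +
      pl[cbind(c(r1), c(c0))] * tr * (1 - tc) +
      pl[cbind(c(r0), c(c1))] * (1 - tr) * tc +
      pl[cbind(c(r1), c(c1))] * tr * tc
  }
  rn <- pmin(pmax(round(src_r), 1), H)
  cn <- pmin(pmax(round(src_c), 1), W)
  m <- matrix(as.matrix(mask)[cbind(c(rn), c(cn))], H, W)
  list(image = out, mask = m)
}
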