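# Palette codec, file IO, preprocessing and augmentation.

test_that("palette codec: label convention and exact round trips", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_identical(as.integer(decode_color_mask(px(0, 0, 0))), 0L)
  expect_identical(as.integer(decode_color_mask(px(0, 1, 0))), 1L)
  expect_identical(as.integer(decode_color_mask(px(1, 0, 0))), 2L)
  # 0-255 scale accepted too
  expect_identical(as.integer(decode_color_mask(px(255, 0, 0))), 2L)
  # antialiased pixel snaps to the nearest palette colour
  expect_identical(as.integer(decode_color_mask(px(10 / 255, 200 / 255,
                                                   30 / 255))), 1L)

  set.seed(1)
  m <- matrix(sample(0:2, 63, TRUE), 7, 9)
  expect_identical(decode_color_mask(encode_color_mask(m)), m)
  img <- encode_color_mask(m)
  expect_identical(encode_color_mask(decode_color_mask(img)), img)

  expect_identical(encode_color_mask(matrix(0L, 2, 2)),
                   array(0, c(2, 2, 3)))
  expect_error(encode_color_mask(matrix(5L, 2, 2)), "labels")
  expect_error(decode_color_mask(matrix(0, 2, 2)), "H x W x 3")
})

test_that("PNG mask files survive a write/read cycle", {
  set.seed(2)
  m <- matrix(sample(0:2, 64 * 64, TRUE), 64)
  f <- tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f), m)
  # dataset directory layout
  pairs <- list(list(image = array(runif(16 * 16 * 3), c(16, 16, 3)),
                     mask = matrix(sample(0:2, 256, TRUE), 16)))
  dd <- tempfile()
  write_dataset(pairs, dd)
  back <- read_dataset(dd)
  expect_identical(back[[1]]$mask, pairs[[1]]$mask)
  expect_equal(back[[1]]$image, pairs[[1]]$image, tolerance = 1 / 255)
})

test_that("preprocess: resize, standardization and label safety", {
  set.seed(3)
  img <- array(runif(96 * 130 * 3), c(96, 130, 3))
  mask <- matrix(sample(c(0L, 2L), 96 * 130, TRUE), 96, 130)
  pp <- preprocess(img, mask, size = c(64, 64))
  expect_identical(dim(pp$image), c(64L, 64L, 3L))
  expect_identical(dim(pp$mask), c(64L, 64L))
  # nearest-neighbour resize introduces no new labels
  expect_true(all(unique(as.vector(pp$mask)) %in% unique(as.vector(mask))))
  expect_error(preprocess(img, matrix(0L, 10, 10)), "disagree")

  # dataset statistics standardize to ~N(0,1) (size kept, no smoothing)
  big <- array(runif(200 * 200 * 3), c(200, 200, 3))
  stats <- compute_norm_stats(list(list(image = big)))
  std <- preprocess(big, size = c(200, 200), stats = stats)$image
  for (c in 1:3) {
    expect_lt(abs(mean(std[, , c])), 0.05)
    expect_lt(abs(sd(std[, , c]) - 1), 0.1)
  }
})

test_that("augmentation: label consistency, involution, determinism", {
  set.seed(4)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mask <- matrix(sample(0:2, 1024, TRUE), 32)

  # horizontal + vertical flip applied twice is the identity
  f1 <- weedseg:::flip_v(weedseg:::flip_h(img))
  expect_identical(weedseg:::flip_v(weedseg:::flip_h(f1)), img)

  # blur never touches the mask
  a <- augment(img, mask, seed = 7, blur_prob = 1)
  expect_identical(a$mask %in% c(mask), rep(TRUE, length(mask)))

  # fixed seed gives a bit-identical augmented pair
  b <- augment(img, mask, seed = 7, blur_prob = 1)
  expect_identical(a, b)

  # a flip applied to the image is applied identically to the mask
  set.seed(5)
  found_flip <- FALSE
  for (s in 1:10) {
    aa <- augment(img, mask, seed = s, blur_prob = 0)
    if (!identical(aa$image, img)) {
      found_flip <- TRUE
      # reconstruct the mask transform from the image transform
      for (tf in list(weedseg:::flip_h, weedseg:::flip_v,
                      function(z) weedseg:::flip_v(weedseg:::flip_h(z)))) {
        if (identical(tf(img), aa$image))
          expect_identical(tf(mask), aa$mask)
      }
    }
  }
  expect_true(found_flip)
})

test_that("optional offline transforms keep pairs aligned", {
  img <- array(0, c(24, 24, 3))
  img[8:16, 8:16, 2] <- 1
  mask <- matrix(0L, 24, 24)
  mask[8:16, 8:16] <- 1L
  for (out in list(miscut_transform(img, mask, shear = 0.15),
                   elastic_transform(img, mask, alpha = 3, seed = 2))) {
    expect_identical(dim(out$image), dim(img))
    expect_true(all(out$mask %in% 0:1))
    # the warped green region and the warped label stay essentially aligned
    green <- out$image[, , 2] > 0.5
    agree <- mean(green == (out$mask == 1L))
    expect_gt(agree, 0.95)
  }
})
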