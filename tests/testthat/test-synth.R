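# The procedural scene generator and split dataset builder.

test_that("scene spec validation", {
  expect_error(scene_spec(weed_radius_range = c(10, 30),
                          crop_radius_range = c(12, 20)), "strictly smaller")
  expect_error(scene_spec(overlap_prob = 1.5), "overlap_prob")
  expect_error(generate_synthetic_scene(
    scene_spec(size = c(32, 32), crop_radius_range = c(20, 30),
               weed_radius_range = c(2, 3))), "does not fit")
})

test_that("scenes are seed-deterministic with aligned image and mask", {
  sp <- scene_spec(size = c(64, 64), n_crops = 2, n_weeds = 5,
                   crop_radius_range = c(8, 11),
                   weed_radius_range = c(2, 4), seed = 9)
  s1 <- generate_synthetic_scene(sp)
  s2 <- generate_synthetic_scene(sp)
  expect_identical(s1, s2)
  expect_identical(dim(s1$image), c(64L, 64L, 3L))
  expect_identical(dim(s1$mask), c(64L, 64L))
  expect_true(all(s1$mask %in% 0:2))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # different seed, different scene
  sp$seed <- 10L
  expect_false(identical(generate_synthetic_scene(sp), s1))
})

test_that("plant structure: weed-free scenes and crop component count", {
  sp <- scene_spec(size = c(96, 96), n_crops = 3, n_weeds = 0,
                   crop_radius_range = c(10, 14),
                   weed_radius_range = c(2, 4), seed = 1)
  expect_identical(sum(generate_synthetic_scene(sp)$mask == 2L), 0L)

  # overlap_prob = 0, n_crops = 3: exactly 3 connected crop components
  for (seed in c(2, 5, 11)) {
    sp2 <- scene_spec(size = c(96, 96), n_crops = 3, n_weeds = 6,
                      crop_radius_range = c(10, 14),
                      weed_radius_range = c(2, 4), overlap_prob = 0,
                      seed = seed)
    sc <- generate_synthetic_scene(sp2)
    expect_identical(count_components(sc$mask, 1L), 3)
  }
})

test_that("weed-pixel fraction grows with n_weeds", {
  frac <- function(nw) {
    mean(vapply(1:4, function(seed) {
      sp <- scene_spec(size = c(96, 96), n_crops = 2, n_weeds = nw,
                       crop_radius_range = c(10, 13),
                       weed_radius_range = c(2, 4), seed = seed)
      mean(generate_synthetic_scene(sp)$mask == 2L)
    }, numeric(1)))
  }
  f <- c(frac(2), frac(8), frac(20))
  expect_true(f[1] < f[2] && f[2] < f[3])
})

test_that("dataset splits: sizes, leakage guard, per-split reproduction", {
  sp <- scene_spec(size = c(48, 48), n_crops = 2, n_weeds = 4,
                   crop_radius_range = c(6, 9), weed_radius_range = c(2, 3))
  ds <- generate_synthetic_dataset(sp, 6, 2, 2, seed = 21)
  expect_identical(lengths(ds)[c("train", "val", "test")],
                   c(train = 6L, val = 2L, test = 2L))

  # no image is bit-identical across splits
  digests <- lapply(ds, function(split)
    vapply(split, function(p) paste(format(sum(p$image * seq_along(p$image)),
                                           digits = 17)), character(1)))
  expect_identical(anyDuplicated(unlist(digests)), 0L)

  # the same master seed regenerates every split
  ds2 <- generate_synthetic_dataset(sp, 6, 2, 2, seed = 21)
  expect_identical(ds, ds2)

  # each split is reproducible independently from its own seed stream
  ss <- attr(ds, "split_seeds")
  sp2 <- sp
  sp2$seed <- ss[2] + 1L
  expect_identical(generate_synthetic_scene(sp2), ds$val[[1]])

  expect_error(generate_synthetic_dataset(sp, 0, 1, 1), "positive")
})
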