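# Training protocol: schedule, checkpoints, reproducibility.

test_that("cosine annealing schedule", {
  cfg <- train_config(lr = 0.001, epochs = 150)
  expect_equal(cosine_lr(0, cfg), 0.001)
  expect_equal(cosine_lr(150, cfg), 0, tolerance = 1e-18)
  expect_equal(cosine_lr(75, cfg), 0.0005)
  expect_error(cosine_lr(-1, cfg), "epoch")
  expect_error(cosine_lr(151, cfg), "epoch")
})

test_that("config validation happens before any training step", {
  expect_error(train_config(lr = 0), "positive")
  expect_error(train_config(checkpoint_every = 20, epochs = 10),
               "must not exceed")
  set.seed(1)
  net <- build_variant("U_VI")
  expect_error(train_network(net, list()), "empty")
  expect_error(train_network(net, list(1), cfg = list()), "train_config")
})

test_that("checkpoint schedule, round trip, and seeded reproducibility", {
  set.seed(2)
  pairs <- make_training_pairs(2, 32, seed0 = 60, n_crops = 1,
                               crop_r = c(6, 9), n_weeds = 3,
                               weed_r = c(2, 3))
  cfg <- train_config(batch_size = 2, epochs = 10, checkpoint_every = 5,
                      seed = 5)
  dir <- tempfile()
  set.seed(3)
  net <- build_variant("U_VI")
  fit <- train_network(net, pairs, cfg, checkpoint_dir = dir)
  saved <- list.files(dir)
  expect_true(all(c("epoch_005.rds", "epoch_010.rds", "last.rds") %in% saved))
  expect_identical(nrow(fit$history), 10L)
  expect_true(all(is.finite(fit$history$loss)))
  # learning rate follows the cosine schedule
  expect_equal(fit$history$lr, vapply(0:9, cosine_lr, numeric(1), cfg = cfg))

  # saved checkpoint evaluates identically twice
  r1 <- evaluate_checkpoint(file.path(dir, "last.rds"), pairs)
  r2 <- evaluate_checkpoint(file.path(dir, "last.rds"), pairs)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # and matches the in-memory network
  expect_equal(miou(r1), miou(evaluate_dataset(fit$net, pairs)))

  # identical seeds give identical final losses
  set.seed(3)
  net2 <- build_variant("U_VI")
  fit2 <- train_network(net2, pairs, cfg)
  expect_equal(fit$history$loss, fit2$history$loss, tolerance = 1e-6)

  # training reduces the loss on this tiny problem
  expect_lt(min(fit$history$loss), fit$history$loss[1])
})

test_that("validation tracking records MIOU and pixel accuracy", {
  set.seed(4)
  pairs <- make_training_pairs(2, 32, seed0 = 70, n_crops = 1,
                               crop_r = c(6, 9), n_weeds = 2,
                               weed_r = c(2, 3))
  cfg <- train_config(batch_size = 2, epochs = 2, checkpoint_every = 2,
                      seed = 6)
  net <- build_variant("U_VI")
  fit <- train_network(net, pairs, cfg, val_data = pairs[1])
  expect_true(all(c("val_miou", "val_pixel_accuracy") %in%
                    names(fit$history)))
  expect_true(all(fit$history$val_miou >= 0 & fit$history$val_miou <= 1))
})
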