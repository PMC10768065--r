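# Confusion counting and the metric suite.

test_that("confusion counts: exactness, additivity, error handling", {
  # 2x2 toy grid, enumerated by hand over its four pixels
  truth <- matrix(c(1L, 0L, 0L, 2L), 2)
  pred <- matrix(c(1L, 0L, 1L, 0L), 2)
  cc <- confusion_counts(pred, truth, 3)
  r1 <- cc[cc$class == 1, ]
  expect_identical(c(r1$tp, r1$fp, r1$fn, r1$tn), c(1, 1, 0, 2))

  # perfect prediction: no false pixels anywhere
  cc0 <- confusion_counts(truth, truth, 3)
  expect_true(all(cc0$fp == 0) && all(cc0$fn == 0))

  # tp+fp+fn+tn is the pixel count for every class
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 4))

  # additivity over an image set
  m1 <- matrix(sample(0:2, 24, TRUE), 4)
  m2 <- matrix(sample(0:2, 24, TRUE), 4)
  p1 <- matrix(sample(0:2, 24, TRUE), 4)
  p2 <- matrix(sample(0:2, 24, TRUE), 4)
  joint <- confusion_counts(array(c(p1, p2), c(4, 6, 2)),
                            array(c(m1, m2), c(4, 6, 2)), 3)
  summed <- sum_confusion(confusion_counts(p1, m1, 3),
                          confusion_counts(p2, m2, 3))
  expect_equal(tibble::as_tibble(joint), tibble::as_tibble(summed))

  expect_error(confusion_counts(matrix(3L, 2, 2), matrix(0L, 2, 2), 3),
               "out of range")
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 2, 3), 3),
               "shapes differ")
})

test_that("metric formulas and zero-denominator conventions", {
  cc <- confusion_from_counts(tp = c(10, 0, 0), fp = c(5, 0, 3),
                              fn = c(2, 0, 0), tn = c(83, 100, 97))
  expect_equal(precision(cc, 0), 10 / 15)
  expect_equal(recall(cc, 0), 10 / 12)
  expect_equal(iou(cc, 0), 10 / 17)
  # class 1: absent and never predicted -> 1 by convention
  expect_identical(c(iou(cc, 1), precision(cc, 1), recall(cc, 1),
                     f1score(cc, 1)), c(1, 1, 1, 1))
  # class 2: predicted but absent -> own denominators give 0
  expect_identical(precision(cc, 2), 0)
  expect_identical(recall(cc, 2), 0)
  expect_identical(iou(cc, 2), 0)
})

test_that("F1 <-> IOU identity holds exactly over random tables", {
  expect_identical(f1_to_iou(0), 0)
  expect_identical(f1_to_iou(1), 1)
  expect_error(f1_to_iou(1.2), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:20) {
    cc <- confusion_from_counts(tp = sample(1e6, 3), fp = sample(1e5, 3),
                                fn = sample(1e5, 3), tn = sample(1e7, 3))
    for (cls in 0:2)
      expect_equal(f1_to_iou(f1score(cc, cls)), iou(cc, cls),
                   tolerance = 1e-9)
  }
})

test_that("metrics are invariant under pixel-order permutation", {
  set.seed(4)
  truth <- matrix(sample(0:2, 64, TRUE), 8)
  pred <- matrix(sample(0:2, 64, TRUE), 8)
  perm <- sample(64)
  r1 <- metrics_report(confusion_counts(pred, truth, 3))
  r2 <- metrics_report(confusion_counts(matrix(pred[perm], 8),
                                        matrix(truth[perm], 8), 3))
  expect_equal(miou(r1), miou(r2))
  expect_equal(r1$iou, r2$iou)
})

test_that("report structure: per-class identity, tidy/glance", {
  set.seed(5)
  cc <- confusion_from_counts(tp = sample(1e4, 3), fp = sample(1e3, 3),
                              fn = sample(1e3, 3), tn = sample(1e5, 3))
  rep <- metrics_report(cc)
  expect_equal(miou(rep), mean(rep$iou))
  expect_equal(rep$iou, f1_to_iou(rep$f1), tolerance = 1e-9)
  td <- tidy(rep)
  expect_true(all(c("class", "iou", "precision", "recall", "f1") %in%
                    names(td)))
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$miou, miou(rep))
})

test_that("evaluate_dataset: perfect nets, determinism, native-size masks", {
  set.seed(6)
  net <- build_variant("U_VI")
  sc <- make_training_pairs(2, 32, seed0 = 40, n_crops = 1,
                            n_weeds = 3, crop_r = c(5, 7),
                            weed_r = c(2, 3))
  rep1 <- evaluate_dataset(net, sc)
  rep2 <- evaluate_dataset(net, sc)
  expect_equal(tibble::as_tibble(rep1), tibble::as_tibble(rep2))
  expect_error(evaluate_dataset(net, list()), "non-empty")

  # a prediction identical to the truth scores MIOU 1 regardless of the net:
  # feed the net's own argmax back as the truth
  pred <- predict(net, feature_map(sc[[1]]$image))
  fake <- list(list(image = sc[[1]]$image, mask = array(pred, c(32, 32))))
  expect_equal(miou(evaluate_dataset(net, fake)), 1)

  # masks at native (larger) resolution: predictions are upsampled nearest,
  # total pixel count follows the mask
  big <- list(list(image = sc[[1]]$image,
                   mask = resize_nearest(array(sc[[1]]$mask, c(32, 32)),
                                         c(64, 64))))
  repb <- evaluate_dataset(net, big)
  expect_identical(unique(repb$tp + repb$fp + repb$fn + repb$tn), 64 * 64)
})
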