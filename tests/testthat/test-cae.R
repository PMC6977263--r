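# CAE segmenter: loss functions, overlap metrics, toy training.

test_that("the Jaccard loss hits its closed-form anchor points", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(jaccard_loss(t, t), 0)
  expect_equal(jaccard_loss(1 - t, t), 1)
  # uniform 0.5 probabilities vs fraction-f truth: direct-sum oracle
  truth <- matrix(0, 10, 10); truth[1:4, ] <- 1          # f = 0.4
  p <- matrix(0.5, 10, 10)
  Si <- sum(p * truth); Su <- sum(p + truth - p * truth)
  expect_equal(jaccard_loss(p, truth), 1 - Si / Su)
  expect_error(jaccard_loss(matrix(0.5, 2, 3), matrix(0, 3, 2)), "shape")
})

test_that("pixelwise F1 and IoU follow their closed forms", {
  a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
  a[1:2, 1:4] <- TRUE                     # 8 predicted
  b[1:2, 1:4] <- TRUE
  a[3, 1:2] <- TRUE                       # 2 false positives
  b[4, 1:2] <- TRUE                       # 2 false negatives
  m <- f1_iou(a, b)
  expect_equal(m$F1, 0.8)
  expect_equal(m$IoU, 2 / 3)
  same <- f1_iou(b, b)
  expect_equal(same$F1, 1); expect_equal(same$IoU, 1)
  disj <- f1_iou(a & !b, b & !a)
  expect_equal(disj$F1, 0); expect_equal(disj$IoU, 0)
  expect_warning(f1_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("F1 and IoU obey the algebraic identity F1 = 2 IoU/(1+IoU)", {
  set.seed(6)
  for (rep in 1:10) {
    a <- matrix(runif(100) > 0.5, 10, 10)
    b <- matrix(runif(100) > 0.5, 10, 10)
    m <- f1_iou(a, b)
    expect_equal(m$F1, 2 * m$IoU / (1 + m$IoU), tolerance = 1e-12)
    expect_gte(m$F1, m$IoU)
  }
})

test_that("the forward pass of an all-zero image is finite", {
  spec <- cae_spec(feature_maps = 4, patch_px = 8)
  wts <- rootarch:::cae_init_weights(spec, 1)
  x <- matrix(0, 64, 3)
  p <- rootarch:::cae_forward(x, wts, rootarch:::spatial_idx(8, 8))$prob
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(nrow(p), 64)               # output shape equals input shape
})

toy_pairs <- function(n, seed0 = 200) {
  lapply(seq_len(n), function(i) {
    sc <- render_blueprint(sample_blueprint(
      seed = seed0 + i, canvas = c(120, 100), depth_px = c(70, 95),
      n_lat = c(1, 1), lat_length_px = c(30, 45)))
    list(image = sc$image, mask = sc$truth$mask)
  })
}

test_that("toy training is deterministic per seed and learns the colours", {
  pairs <- toy_pairs(12)
  spec <- cae_spec(feature_maps = 8, patch_px = 24)
  cfg <- cae_config(epochs = 30, folds = 2, seed = 3)
  m1 <- train_cae(pairs, spec, cfg)
  m2 <- train_cae(pairs, spec, cfg)
  expect_identical(m1$cv$folds, m2$cv$folds)
  expect_identical(m1$weights, m2$weights)
  expect_gt(m1$cv$IoU, 0.5)
  expect_gte(m1$cv$F1, m1$cv$IoU)
  # training loss decreases over epochs
  expect_lt(tail(m1$epoch_loss, 1), m1$epoch_loss[1])
  # too few pairs for the folds
  expect_error(train_cae(pairs[1:3], spec, cae_config(folds = 5)), "pairs")
})

test_that("thresholding a trained segmenter behaves at the extremes", {
  pairs <- toy_pairs(12)
  spec <- cae_spec(feature_maps = 8, patch_px = 24)
  mdl <- train_cae(pairs, spec, cae_config(epochs = 30, folds = 2, seed = 3))
  img <- pairs[[1]]$image
  m_all <- segment_cae(mdl, img, threshold = 0, min_object_px = 0)
  expect_true(all(m_all$pixels))
  m_none <- segment_cae(mdl, img, threshold = 1, min_object_px = 0)
  expect_false(any(m_none$pixels))
  expect_true("no_root" %in% m_none$flag)
  # training-scene sanity: reasonable overlap with its own truth
  m_half <- segment_cae(mdl, img, threshold = 0.5, min_object_px = 20)
  expect_gt(f1_iou(m_half, pairs[[1]]$mask)$IoU, 0.5)
})
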