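test_that("layer arithmetic reproduces the architecture anchor", {
  s <- layer_output_shapes(cnn_config(), c(16L, 16L, 200L))
  expect_equal(s$conv1, c(10, 10, 194, 8))
  expect_equal(s$conv2, c(6, 6, 190, 8))
  expect_equal(s$pool, c(3, 3, 95, 8))
  expect_equal(s$flatten, 6840)
  # a cube that fits conv1 exactly
  expect_equal(layer_output_shapes(cnn_config(), c(20L, 20L, 20L))$conv1,
               c(14, 14, 14, 8))
  expect_error(layer_output_shapes(cnn_config(), c(6L, 6L, 6L)), "kernel")
})

test_that("block normalization follows the unit-range rule", {
  b <- array(seq(10, 30, length.out = 8), c(2, 2, 2))
  nb <- normalize_block(b)
  expect_equal(range(nb), c(0, 1))
  expect_equal(normalize_block(array(c(10, 20, 30, 30), c(2, 2, 1)))[2, 1, 1],
               0.5)
  expect_equal(normalize_block(array(7, c(2, 2, 2))),
               array(0, c(2, 2, 2)))
  b01 <- array(c(0, 1, runif(6)), c(2, 2, 2))
  expect_equal(normalize_block(normalize_block(b01)), normalize_block(b01))
  expect_error(normalize_block(array(c(NA, 1:7), c(2, 2, 2))), "finite")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(51)
  blocks <- array(runif(16 * 16 * 12 * 4), c(16, 16, 12, 4))
  labels <- c(0L, 1L, 1L, 0L)
  cfg <- cnn_config(seed = 5)
  w <- microflow:::init_weights(layer_output_shapes(cfg, c(16, 16, 12)), cfg)
  g <- microflow:::cnn_grad_cpp(blocks, labels, w, cfg$mlp_hidden, TRUE)
  h <- 1e-3
  for (nm in c("W1", "W2", "Wh", "Wo")) {
    idx <- sample(length(w[[nm]]), 2)
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      num <- (microflow:::cnn_grad_cpp(blocks, labels, wp,
                                       cfg$mlp_hidden, TRUE)$loss -
              microflow:::cnn_grad_cpp(blocks, labels, wm,
                                       cfg$mlp_hidden, TRUE)$loss) / (2 * h)
      expect_equal(g$grad[[nm]][i], num, tolerance = 0.05)
    }
  }
})

test_that("the network learns an easily separable flow signal", {
  fx <- easy_blocks(120, depth = 24, seed = 52)
  cfg <- cnn_config(max_epochs = 10, seed = 52)
  model <- train_cnn(fx$blocks, fx$labels, cfg)
  h <- model$history
  expect_lt(h$error_rate[nrow(h)], 0.1)
  expect_true(all(is.finite(h$loss)))
  # loss trend is non-increasing (moving average over up to 5 epochs)
  ma <- stats::filter(h$loss, rep(1 / 3, 3), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])

  p <- predict(model, fx$blocks)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p >= 0.5) == fx$labels), 0.9)
  # inference is deterministic
  expect_identical(p, predict(model, fx$blocks))
  # single block helper agrees with the batch path
  expect_equal(predict_pixel(model, fx$blocks[, , , 1]), p[1])
})

test_that("training refuses degenerate label sets", {
  fx <- easy_blocks(8, depth = 12, seed = 53)
  expect_error(train_cnn(fx$blocks, rep(TRUE, 8), cnn_config()),
               "each class")
  expect_error(train_logistic_baseline(fx$blocks, rep(FALSE, 8)),
               "each class")
})

test_that("training is reproducible for a fixed seed", {
  fx <- easy_blocks(20, depth = 12, seed = 54)
  cfg <- cnn_config(max_epochs = 3, seed = 7)
  m1 <- train_cnn(fx$blocks, fx$labels, cfg)
  m2 <- train_cnn(fx$blocks, fx$labels, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("vessel decisions follow threshold and strict majority", {
  d <- decide_vessel(c(0.9, 0.8, 0.7, 0.2))
  expect_equal(d$flowing_fraction, 0.75)
  expect_true(d$vessel_flowing)

  expect_false(decide_vessel(c(0.1, 0.2, 0.3, 0.4))$vessel_flowing)
  # exactly half is NOT flowing (strict majority)
  half <- decide_vessel(c(0.9, 0.9, 0.1, 0.1))
  expect_equal(half$flowing_fraction, 0.5)
  expect_false(half$vessel_flowing)
  # threshold boundary: p == 0.5 counts as flowing
  expect_true(decide_vessel(c(0.5, 0.5, 0.5))$vessel_flowing)
  expect_error(decide_vessel(numeric(0)), "empty")
})

test_that("raising a pixel probability never un-flows a vessel", {
  set.seed(55)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    before <- decide_vessel(p)$vessel_flowing
    j <- sample(length(p), 1)
    p[j] <- min(1, p[j] + runif(1))
    after <- decide_vessel(p)$vessel_flowing
    expect_false(before && !after)
  }
})

test_that("cross-validation folds are stratified and scored per fold", {
  fx <- easy_blocks(45, depth = 24, seed = 57)
  cv <- cross_validate_cnn(fx$blocks, fx$labels, k = 3,
                           cnn_config(max_epochs = 4, seed = 57))
  expect_equal(nrow(cv), 3L)
  expect_equal(sum(cv$n), 45L)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_equal(attr(cv, "accuracy"),
               sum(cv$accuracy * cv$n) / 45)
})

test_that("the logistic baseline uses one coefficient per block voxel", {
  fx <- easy_blocks(12, depth = 200, seed = 56)
  base <- train_logistic_baseline(fx$blocks, fx$labels, seed = 1)
  cf <- coef(base)
  expect_length(cf$coefficients, 16 * 16 * 200) # 51,200
  p <- predict(base, fx$blocks)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p >= 0.5) == fx$labels), 0.5)
  base2 <- train_logistic_baseline(fx$blocks, fx$labels, seed = 1)
  expect_identical(coef(base2), cf)
})
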