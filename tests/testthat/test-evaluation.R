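test_that("confusion counts match their definition", {
  cm <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(2, 1, 0, 0))
  cm2 <- confusion(c(0, 0, 1), c(1, 1, 0))
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  expect_error(confusion(c(1, 0), c(1)), "length mismatch")
})

test_that("confusion agrees with an element-wise counting oracle", {
  set.seed(61)
  pred <- runif(1000) < 0.5
  truth <- runif(1000) < 0.6
  cm <- confusion(pred, truth)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(1000)) { # independent loop oracle
    if (pred[i] && truth[i]) tp <- tp + 1
    else if (!pred[i] && !truth[i]) tn <- tn + 1
    else if (pred[i]) fp <- fp + 1
    else fn <- fn + 1
  }
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(tp, tn, fp, fn))
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 1000)
})

test_that("metric derivations are exact and undefined cases stay NA", {
  m <- metrics(confusion_matrix(tp = 3179, tn = 787, fp = 255, fn = 183))
  expect_equal(m$accuracy, (3179 + 787) / 4404)
  expect_equal(m$f1, 2 * 3179 / (2 * 3179 + 255 + 183))
  # harmonic-mean identity
  expect_equal(m$f1, 2 / (1 / m$positive_precision + 1 / m$sensitivity),
               tolerance = 1e-12)

  deg <- metrics(confusion_matrix(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_equal(deg$accuracy, 1)
  expect_true(is.na(deg$sensitivity))
  expect_true(is.na(deg$positive_precision))
})

test_that("accuracy is the prevalence-weighted mean of sens and spec", {
  set.seed(62)
  for (i in 1:20) {
    cm <- confusion_matrix(tp = sample(0:50, 1) + 1, tn = sample(0:50, 1) + 1,
                           fp = sample(0:50, 1), fn = sample(0:50, 1))
    n <- cm$tp + cm$tn + cm$fp + cm$fn
    m <- metrics(cm)
    spec <- cm$tn / (cm$tn + cm$fp)
    expect_equal(m$accuracy,
                 m$sensitivity * (cm$tp + cm$fn) / n +
                   spec * (cm$tn + cm$fp) / n)
    vals <- unlist(m)
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  }
})

test_that("end-to-end rates follow the detection/error protocol", {
  # 10 true flowing crossings; pipeline finds 8 of them and marks one
  # artifact flowing -> detection 8/10, error 1/9
  truth <- data.frame(axis = "h", line = 1L, start = 1L, end = 1L,
                      center_row = seq(10, 100, by = 10),
                      center_col = 50L, vessel_id = 1:10, flowing = TRUE)
  dec <- data.frame(center_row = c(seq(10, 80, by = 10), 200),
                    center_col = 50L, vessel_flowing = TRUE)
  ev <- end_to_end_eval(dec, truth)
  expect_equal(ev$detection_rate, 0.8)
  expect_equal(ev$error_rate, 1 / 9)

  # perfect pipeline
  perfect <- data.frame(center_row = truth$center_row,
                        center_col = truth$center_col,
                        vessel_flowing = TRUE)
  ev2 <- end_to_end_eval(perfect, truth)
  expect_equal(ev2$detection_rate, 1)
  expect_equal(ev2$error_rate, 0)

  # pipeline that marks nothing: no detections, error undefined
  none <- data.frame(center_row = integer(0), center_col = integer(0),
                     vessel_flowing = logical(0))
  ev3 <- end_to_end_eval(none, truth)
  expect_equal(ev3$detection_rate, 0)
  expect_true(is.na(ev3$error_rate))

  expect_error(end_to_end_eval(perfect, truth[0, ]), "empty")
})

test_that("crossing labeling matches by center distance", {
  truth <- data.frame(center_row = c(10, 40), center_col = c(10, 40),
                      flowing = c(TRUE, FALSE))
  samples <- data.frame(sample_id = 1:3,
                        center_row = c(11, 41, 70),
                        center_col = c(10, 39, 70))
  out <- label_crossings(samples, truth, match_radius_px = 3)
  expect_equal(out$label, c(TRUE, FALSE, FALSE))
  expect_equal(out$matched, c(TRUE, TRUE, FALSE))
})
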