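test_that("ridge points localize a horizontal Gaussian ridge sub-pixel", {
  img <- gauss_ridge_image(64, 128, row = 32.3, width = 3)
  pts <- steger_detect(img, width_px = 3)
  expect_gt(nrow(pts), 0)
  # along >= 95% of the ridge length, a point within 0.5 px of the crest
  margin <- 6
  cols <- (1 + margin):(128 - margin)
  hit <- vapply(cols, function(c_) {
    near <- pts[pts$pixel_col == c_, ]
    nrow(near) > 0 && any(abs(near$row - 32.3) <= 0.5)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # normals point across the ridge
  core <- pts[abs(pts$row - 32.3) <= 0.5 & pts$pixel_col %in% cols, ]
  expect_true(all(abs(abs(core$normal_row) - 1) < 0.1))
  expect_equal(sqrt(core$normal_row^2 + core$normal_col^2),
               rep(1, nrow(core)), tolerance = 1e-6)
})

test_that("a rotated ridge yields a similar point count and true normals", {
  img0 <- gauss_ridge_image(96, 96, row = 48.2, width = 3)
  img45 <- gauss_ridge_image(96, 96, row = 48.2, width = 3, angle_deg = 45)
  # fixed absolute thresholds so the two fixtures are treated alike
  pts0 <- steger_detect(img0, width_px = 3, low_thresh = 0.05,
                        high_thresh = 0.1)
  pts45 <- steger_detect(img45, width_px = 3, low_thresh = 0.05,
                         high_thresh = 0.1)
  # interior window only: border effects differ between the two
  keep0 <- pts0[pts0$pixel_col > 10 & pts0$pixel_col < 86, ]
  keep45 <- pts45[pts45$pixel_col > 10 & pts45$pixel_col < 86 &
                    pts45$pixel_row > 10 & pts45$pixel_row < 86, ]
  expect_lt(abs(nrow(keep45) - nrow(keep0)) / nrow(keep0), 0.1)
  # normals within 5 degrees of the true normal (+/- [cos45, sin45])
  ang <- abs(keep45$normal_row * cos(pi / 4) - keep45$normal_col * sin(pi / 4))
  expect_true(all(acos(pmin(ang, 1)) < 5 * pi / 180))
})

test_that("a constant image yields no ridge points", {
  expect_equal(nrow(steger_detect(matrix(1, 32, 32))), 0)
  expect_error(steger_detect(matrix(1, 32, 32), sigma = 0), "positive")
})

test_that("binarization marks exactly the emitting pixels", {
  empty <- steger_detect(matrix(1, 16, 16))
  m <- link_and_binarize(empty, c(16, 16))
  expect_false(any(m$mask))

  pts <- data.frame(row = c(2.2, 5.0, 9.8), col = c(3.1, 5.5, 12.0),
                    pixel_row = c(2L, 5L, 10L), pixel_col = c(3L, 5L, 12L),
                    normal_row = c(1, 1, 1), normal_col = c(0, 0, 0),
                    strength = c(1, 1, 1))
  m <- link_and_binarize(pts, c(16, 16))
  expect_equal(sum(m$mask), 3L)
  expect_true(all(m$mask[cbind(pts$pixel_row, pts$pixel_col)]))
})

test_that("ridge points of a Gaussian ridge form a connected path", {
  img <- gauss_ridge_image(64, 64, row = 20, width = 3)
  pts <- steger_detect(img, width_px = 3)
  m <- link_and_binarize(pts, dim(img))
  # one component spans (almost) the full width
  comp <- m$components
  main <- which.max(m$component_sizes)
  cols_hit <- unique(which(comp == main, arr.ind = TRUE)[, 2])
  expect_gte(length(cols_hit), 64 * 0.9)
})

test_that("morphological close bridges 1-px gaps into one component", {
  mask <- matrix(FALSE, 16, 32)
  mask[8, 3:12] <- TRUE
  mask[8, 14:23] <- TRUE # 1-px gap at col 13
  m <- postprocess_map(link_and_binarize_from_mask(mask), close_radius = 1,
                       min_segment_px = 4)
  expect_equal(length(m$component_sizes), 1L)
  expect_gte(m$component_sizes[1], 21L)
})

test_that("components shorter than 4 pixels are removed, 4-px kept", {
  mask <- matrix(FALSE, 16, 16)
  mask[2, 2:4] <- TRUE   # 3 px -> removed
  mask[10, 2:5] <- TRUE  # 4 px -> kept
  m <- postprocess_map(link_and_binarize_from_mask(mask), close_radius = 0,
                       min_segment_px = 4)
  expect_false(any(m$mask[2, ]))
  expect_equal(sum(m$mask[10, ]), 4L)

  empty <- postprocess_map(link_and_binarize_from_mask(matrix(FALSE, 8, 8)),
                           close_radius = 1, min_segment_px = 4)
  expect_false(any(empty$mask))
  expect_error(postprocess_map(empty, close_radius = -1), ">= 0")
})

test_that("postprocessing is idempotent and monotone in the right direction", {
  set.seed(21)
  mask <- matrix(runif(48 * 48) < 0.12, 48, 48)
  m0 <- link_and_binarize_from_mask(mask)
  once <- postprocess_map(m0, close_radius = 1, min_segment_px = 4)
  twice <- postprocess_map(once, close_radius = 1, min_segment_px = 4)
  expect_identical(once$mask, twice$mask)

  # closing never removes true pixels ...
  closed <- EBImage::imageData(EBImage::closing(
    EBImage::Image(mask * 1), matrix(1, 3, 3))) > 0.5
  expect_true(all(closed[mask]))
  # ... and pruning never adds any beyond the closed mask
  expect_true(all(closed[once$mask]))
})

test_that("segmentation recalls centerlines of noiseless flowing phantoms", {
  cfg <- phantom_config(shape = c(160L, 160L), n_vessels = c(3L, 3L),
                        flowing_fraction = 1, width_range = c(3, 5),
                        noise_sigma = 0, shot_sigma = 0,
                        static_jitter_sd = 0, n_artifacts = 0L,
                        min_separation = 16)
  ves <- sample_vessel_tree(cfg, seed = 31)
  pv <- render_video(ves, n_frames = 80, cfg, seed = 31)
  sad <- enhance_clahe(compute_sad(pv$stack))
  pts <- steger_detect(sad)
  m <- postprocess_map(link_and_binarize(pts, dim(sad$values)), 1, 4)
  mask_idx <- which(m$mask, arr.ind = TRUE)
  expect_gt(nrow(mask_idx), 0)
  hits <- 0; total <- 0
  for (v in ves) {
    cl <- v$centerline
    keep <- cl$row > 8 & cl$row < 152 & cl$col > 8 & cl$col < 152
    sub <- seq(1, nrow(cl), by = 2)
    sub <- sub[keep[sub]]
    for (i in sub) {
      d <- sqrt((mask_idx[, 1] - cl$row[i])^2 + (mask_idx[, 2] - cl$col[i])^2)
      total <- total + 1
      if (min(d) <= 2) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
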