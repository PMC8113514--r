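test_that("SAD matches its definition on constructed videos", {
  # constant video -> zero
  st <- video_stack(array(7, c(8, 8, 5)))
  expect_true(all(compute_sad(st)$values == 0))

  # one pixel alternating 10, 20, 10, 20 -> |10| * 3
  fr <- array(5, c(4, 4, 4))
  fr[2, 3, ] <- c(10, 20, 10, 20)
  expect_equal(compute_sad(video_stack(fr))$values[2, 3], 30)
})

test_that("SAD is invariant to frame reversal and additive over splits", {
  set.seed(11)
  fr <- array(runif(6 * 6 * 9), c(6, 6, 9))
  st <- video_stack(fr)
  rev_st <- video_stack(fr[, , 9:1])
  expect_equal(compute_sad(st)$values, compute_sad(rev_st)$values)

  # split at a shared frame k: SAD(1..k) + SAD(k..n) == SAD(1..n)
  k <- 4
  left <- compute_sad(video_stack(fr[, , 1:k]))$values
  right <- compute_sad(video_stack(fr[, , k:9]))$values
  expect_equal(left + right, compute_sad(st)$values)
})

test_that("block matching recovers global integer shifts", {
  set.seed(12)
  f0 <- matrix(runif(96 * 96), 96, 96)
  fr <- array(0, c(96, 96, 3))
  fr[, , 1] <- f0
  fr[, , 2] <- f0 # static
  fr[, , 3] <- cbind(f0[, 4:96], f0[, rep(96, 3)]) # content moved left 3 cols
  st <- video_stack(fr, frame_rate_hz = 32.5)
  m <- estimate_motion(st, block_size = 32, search_radius = 8)
  expect_equal(m$drow, c(0, 0, 0))
  expect_equal(m$dcol, c(0, 0, -3))
  expect_equal(m$velocity_px_per_s[2], 0)
  # frame 3 moved 3 px relative to frame 2 -> 3 * 32.5 px/s
  expect_equal(m$velocity_px_per_s[3], 3 * 32.5)
  expect_error(estimate_motion(st, block_size = 128), "block_size")
})

test_that("a 1 px/frame step yields frame-rate velocity", {
  set.seed(13)
  f0 <- matrix(runif(64 * 64), 64, 64)
  fr <- array(0, c(64, 64, 2))
  fr[, , 1] <- f0
  fr[, , 2] <- rbind(f0[2:64, ], f0[64, , drop = FALSE]) # 1 row shift
  st <- video_stack(fr, frame_rate_hz = 32.5)
  m <- estimate_motion(st, block_size = 16, search_radius = 4)
  expect_equal(abs(m$drow[2]), 1)
  expect_equal(m$velocity_px_per_s[2], 32.5)
})

test_that("the motion gate keeps calm frames in order and records indices", {
  set.seed(14)
  scene <- matrix(runif(32 * 32), 32, 32)
  fr <- array(rep(scene, 10), c(32, 32, 10)) +
    array(rnorm(32 * 32 * 10, 0, 0.005), c(32, 32, 10))
  fr <- pmax(fr, 0)
  st <- video_stack(fr)
  motion <- estimate_motion(st, block_size = 16, search_radius = 2)
  # static scene with faint sensor noise: everything kept
  expect_equal(dim(stabilize(st, motion)$frames)[3], 10)

  # hand-built motion estimate: frames 6..9 exceed the gate
  fake <- motion
  fake$velocity_px_per_s <- c(0, 0, 0, 0, 0, 50, 50, 50, 50, 0)
  kept <- stabilize(st, fake, 0.3)
  expect_equal(kept$kept_frames, c(1:5, 10))
  expect_equal(kept$frames, fr[, , c(1:5, 10)], ignore_attr = TRUE)

  # infinite threshold is the identity
  expect_equal(stabilize(st, fake, Inf)$frames, fr, ignore_attr = TRUE)

  fake$velocity_px_per_s <- c(0, rep(50, 9))
  expect_error(stabilize(st, fake, 0.3), "fewer than 2")
})

test_that("stabilized SAD uses surviving neighbor differences", {
  fr <- array(0.5, c(4, 4, 4))
  fr[1, 1, ] <- c(0.1, 0.9, 0.2, 0.3)
  st <- video_stack(fr)
  motion <- estimate_motion(st, block_size = 4, search_radius = 0)
  motion$velocity_px_per_s <- c(0, 50, 0, 0) # drop frame 2
  sub <- stabilize(st, motion, 0.3)
  sad <- compute_sad(sub)
  expect_equal(sad$kept_frame_indices, c(1, 3, 4))
  # |0.2 - 0.1| + |0.3 - 0.2|, the splice difference taken across the gap
  expect_equal(sad$values[1, 1], 0.2)
})

test_that("CLAHE is bounded, safe on constants, and enhances ridges", {
  const <- structure(list(values = matrix(3, 40, 40), n_frames_used = 2,
                          kept_frame_indices = 1:2), class = "sad_image")
  out <- enhance_clahe(const)
  expect_equal(length(unique(as.vector(out$values))), 1L)

  # faint ridge over a wide-range illumination gradient: the classic
  # CLAHE use case
  set.seed(15)
  grad <- matrix(seq(0, 1, length.out = 64), 64, 64, byrow = TRUE)
  ridge <- grad + 0.05 * gauss_ridge_image(64, 64, row = 30, width = 3)
  sad <- structure(list(values = ridge, n_frames_used = 2,
                        kept_frame_indices = 1:2), class = "sad_image")
  eq <- enhance_clahe(sad, tile_grid = 4)
  expect_true(all(eq$values >= 0 & eq$values <= 1))
  on_ridge <- abs(row(ridge) - 30) <= 1
  scaled <- (ridge - min(ridge)) / diff(range(ridge))
  contrast_before <- mean(scaled[on_ridge]) - mean(scaled[!on_ridge])
  contrast_after <- mean(eq$values[on_ridge]) - mean(eq$values[!on_ridge])
  expect_gte(contrast_after, contrast_before)
  expect_error(enhance_clahe(sad, clip_limit = 0), "positive")
})
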