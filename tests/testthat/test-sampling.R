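test_that("grid lines are equidistant and strictly increasing", {
  g <- build_grid(c(400L, 400L), 3)
  expect_equal(g$rows, c(100L, 200L, 300L))
  expect_equal(g$cols, c(100L, 200L, 300L))
  expect_equal(build_grid(c(100L, 100L), 1)$rows, 50L)
  # tiny image: rounding collisions resolved, strictly increasing
  g7 <- build_grid(c(7L, 7L), 3)
  expect_equal(g7$rows, c(2L, 4L, 5L))
  expect_true(all(diff(g7$rows) > 0))
  expect_error(build_grid(c(3L, 3L), 3), "too small")
})

test_that("each mask run along a line becomes exactly one sample", {
  mask <- matrix(FALSE, 100, 100)
  mask[, 40:43] <- FALSE
  mask[20:80, 40:43] <- TRUE # 4-px-wide vertical vessel
  m <- link_and_binarize_from_mask(mask)
  g <- build_grid(c(100L, 100L), 1) # single horizontal+vertical line at 50
  s <- find_intersections(g, m)
  hrow <- s[s$axis == "h", ]
  expect_equal(nrow(hrow), 1L)
  expect_equal(hrow$n_pixels, 4L)
  expect_equal(hrow$start, 40L)
  expect_equal(hrow$end, 43L)
  expect_equal(hrow$center_col, 41L) # lower median of 40..43
  expect_equal(hrow$center_row, 50L)

  expect_equal(nrow(find_intersections(g, link_and_binarize_from_mask(
    matrix(FALSE, 100, 100)))), 0L)
})

test_that("two vessels crossing one line give two disjoint samples", {
  mask <- matrix(FALSE, 60, 60)
  mask[30, 5:9] <- TRUE
  mask[30, 20:22] <- TRUE
  m <- link_and_binarize_from_mask(mask)
  g <- structure(list(rows = 30L, cols = integer(0)),
                 class = "reference_grid")
  s <- find_intersections(g, m)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_pixels, c(5L, 3L))
  # every mask-true pixel on the line is covered exactly once
  covered <- unlist(lapply(seq_len(nrow(s)), function(k) s$start[k]:s$end[k]))
  expect_equal(sort(covered), which(mask[30, ]))
})

test_that("cross-section pixel total equals mask-true pixels on grid lines", {
  set.seed(41)
  mask <- matrix(runif(80 * 80) < 0.2, 80, 80)
  m <- link_and_binarize_from_mask(mask)
  g <- build_grid(c(80L, 80L), 3)
  s <- find_intersections(g, m)
  on_lines <- sum(mask[g$rows, ]) + sum(mask[, g$cols])
  expect_equal(sum(s$n_pixels), on_lines)
})

test_that("blocks are cut with the fixed even-window convention", {
  set.seed(42)
  fr <- array(runif(128 * 128 * 12), c(128, 128, 12))
  st <- video_stack(fr)
  mask <- matrix(FALSE, 128, 128)
  mask[100, 100] <- TRUE
  mask[3, 100] <- TRUE # too close to the border: skipped
  m <- link_and_binarize_from_mask(mask)
  g <- structure(list(rows = c(3L, 100L), cols = integer(0)),
                 class = "reference_grid")
  s <- find_intersections(g, m)
  bl <- extract_blocks(st, s, half_window = 8, n_frames = 12)
  expect_equal(dim(bl$blocks), c(16, 16, 12, 1))
  expect_equal(nrow(bl$skipped), 1L)
  expect_equal(bl$skipped$row, 3L)
  # window spans rows/cols 92..107 around the target pixel at (100, 100)
  expect_equal(bl$blocks[, , , 1], fr[92:107, 92:107, 1:12],
               ignore_attr = TRUE)
  expect_error(extract_blocks(st, s, n_frames = 50), "reduce n_frames")
})

test_that("blocks from an all-constant stack have zero temporal variance", {
  fr <- array(0.5, c(64, 64, 8))
  st <- video_stack(fr)
  mask <- matrix(FALSE, 64, 64); mask[32, 30:33] <- TRUE
  s <- find_intersections(structure(list(rows = 32L, cols = integer(0)),
                                    class = "reference_grid"),
                          link_and_binarize_from_mask(mask))
  bl <- extract_blocks(st, s, n_frames = 8)
  expect_equal(dim(bl$blocks)[4], 4L)
  v <- apply(bl$blocks, 4, function(b) max(apply(b, c(1, 2), var)))
  expect_equal(v, rep(0, 4))
})

test_that("adjacent cross-section blocks overlap by 15 columns", {
  fr <- array(seq_len(64 * 64 * 6) %% 97, c(64, 64, 6)) / 96
  st <- video_stack(fr)
  mask <- matrix(FALSE, 64, 64); mask[32, 30:31] <- TRUE
  s <- find_intersections(structure(list(rows = 32L, cols = integer(0)),
                                    class = "reference_grid"),
                          link_and_binarize_from_mask(mask))
  bl <- extract_blocks(st, s, n_frames = 6)
  expect_equal(bl$blocks[, 2:16, , 1], bl$blocks[, 1:15, , 2],
               ignore_attr = TRUE)
})
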