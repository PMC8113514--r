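# Shared fixtures, all generated in code.

# A bright Gaussian-profile ridge along a given row, optionally rotated.
gauss_ridge_image <- function(H = 64, W = 128, row = 32.0, width = 3,
                              angle_deg = 0) {
  sigma <- width / 2
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (angle_deg == 0) {
    d <- rr - row
  } else {
    th <- angle_deg * pi / 180
    # distance to the line through (row, W/2) at the given angle
    d <- (rr - row) * cos(th) - (cc - W / 2) * sin(th)
  }
  exp(-d^2 / (2 * sigma^2))
}

# Easy labeled blocks: flowing = strong temporal flicker, non-flowing =
# a static spatial pattern plus faint noise. Linearly separable by
# temporal variance.
easy_blocks <- function(n, depth = 24, seed = 1) {
  set.seed(seed)
  blocks <- array(0, dim = c(16, 16, depth, n))
  labels <- rep(c(TRUE, FALSE), length.out = n)
  for (i in seq_len(n)) {
    if (labels[i]) {
      blocks[, , , i] <- array(runif(16 * 16 * depth), c(16, 16, depth))
    } else {
      pattern <- matrix(runif(256), 16, 16)
      blocks[, , , i] <- array(rep(pattern, depth), c(16, 16, depth)) +
        rnorm(16 * 16 * depth, 0, 0.02)
    }
  }
  list(blocks = blocks, labels = labels)
}

# Wrap a raw logical mask as a vessel map.
link_and_binarize_from_mask <- function(mask) microflow:::vessel_map(mask)

# A small, fast phantom for pipeline-level tests.
small_phantom_config <- function(...) {
  phantom_config(shape = c(128L, 128L), n_vessels = c(4L, 5L),
                 min_separation = 10, ...)
}

quiet_pipeline_config <- function(n_frames = 48L, seed = 1L, ...) {
  pipeline_config(n_frames = n_frames, seed = seed,
                  cnn = cnn_config(max_epochs = 6L, seed = seed), ...)
}
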