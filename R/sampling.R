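#' Build the equidistant reference grid
#'
#' Places `n_lines_per_axis` horizontal and vertical reference lines,
#' equidistant from each other and from the image borders: line `k` sits at
#' `round(k * H / (n + 1))`. Duplicate positions after rounding (tiny
#' images) are bumped to keep the lines strictly increasing and inside the
#' image.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param n_lines_per_axis lines per axis (default 3).
#' @return an object of class `reference_grid` with fields `rows`, `cols`.
#' @export
build_grid <- function(shape, n_lines_per_axis = 3L) {
  stopifnot(n_lines_per_axis >= 1)
  place <- function(extent) {
    if (extent < n_lines_per_axis + 2)
      stop("shape too small for ", n_lines_per_axis, " grid lines")
    pos <- round(seq_len(n_lines_per_axis) * extent / (n_lines_per_axis + 1))
    for (k in seq_along(pos)) { # enforce strictly increasing, inside image
      if (k > 1 && pos[k] <= pos[k - 1]) pos[k] <- pos[k - 1] + 1
    }
    pos <- pmin(pos, extent - 1)
    for (k in rev(seq_along(pos))) {
      if (k < length(pos) && pos[k] >= pos[k + 1]) pos[k] <- pos[k + 1] - 1
    }
    as.integer(pos)
  }
  structure(list(rows = place(shape[1]), cols = place(shape[2])),
            class = "reference_grid")
}

#' Find vessel/reference-line intersections
#'
#' Scans every reference line for maximal contiguous runs of mask-true
#' pixels; each run is one intersection sample — the cross-section of a
#' vessel where it crosses the line. Runs are disjoint and every mask-true
#' pixel on a line belongs to exactly one sample. The sample center is the
#' run midpoint (lower median for even runs).
#'
#' @param grid a [build_grid()] result.
#' @param map a `vessel_map` of the same image shape.
#' @return a data frame of class `intersection_samples`, one row per
#'   crossing: `sample_id`, `axis` (`"h"`/`"v"`), `line` (row or column
#'   index), `start`, `end` (run extent along the line), `n_pixels`,
#'   `center_row`, `center_col`.
#' @export
find_intersections <- function(grid, map) {
  stopifnot(inherits(grid, "reference_grid"), inherits(map, "vessel_map"))
  rows <- list()
  scan_line <- function(vals, axis, line) {
    r <- rle(as.vector(vals))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      center <- starts[k] + (r$lengths[k] - 1) %/% 2 # lower median
      rows[[length(rows) + 1]] <<- data.frame(
        axis = axis, line = line,
        start = starts[k], end = ends[k], n_pixels = r$lengths[k],
        center_row = if (axis == "h") line else center,
        center_col = if (axis == "h") center else line)
    }
  }
  for (r in grid$rows) scan_line(map$mask[r, ], "h", r)
  for (c_ in grid$cols) scan_line(map$mask[, c_], "v", c_)
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(axis = character(0), line = integer(0),
                         start = integer(0), end = integer(0),
                         n_pixels = integer(0), center_row = integer(0),
                         center_col = integer(0))
  out <- cbind(sample_id = seq_len(nrow(out)), out)
  class(out) <- c("intersection_samples", "data.frame")
  out
}

#' Extract spatio-temporal data blocks for cross-section pixels
#'
#' For every pixel of every intersection cross-section, cuts the
#' `16 x 16 x n_frames` intensity block that the flow classifier consumes:
#' a 16x16 px neighborhood (the target pixel at offset `(half_window,
#' half_window)`, window spanning `p - 8 .. p + 7` for the default
#' `half_window = 8`) over the first `n_frames` surviving frames. Pixels
#' too close to the border for a full window are skipped and reported.
#'
#' @param stack the (stabilized) [video_stack()].
#' @param samples an [find_intersections()] result.
#' @param half_window half the spatial window (default 8, i.e. 16x16).
#' @param n_frames temporal depth (default 200).
#' @return a list of class `block_set`: `blocks` (array
#'   `[16, 16, n_frames, n_blocks]`), `index` (data frame `block`,
#'   `sample_id`, `row`, `col`), and `skipped` (data frame of border
#'   pixels left out).
#' @export
extract_blocks <- function(stack, samples, half_window = 8L,
                           n_frames = 200L) {
  stopifnot(inherits(stack, "video_stack"),
            inherits(samples, "intersection_samples"))
  d <- dim(stack$frames)
  if (d[3] < n_frames)
    stop("stack has ", d[3], " frames after stabilization but ", n_frames,
         " are required; reduce n_frames")
  win <- 2L * half_window
  px <- cross_section_pixels(samples)
  ok <- px$row - half_window >= 1 & px$row + half_window - 1 <= d[1] &
        px$col - half_window >= 1 & px$col + half_window - 1 <= d[2]
  skipped <- px[!ok, , drop = FALSE]
  px <- px[ok, , drop = FALSE]
  blocks <- array(0, dim = c(win, win, n_frames, nrow(px)))
  if (nrow(px) > 0) {
    for (b in seq_len(nrow(px))) {
      rr <- (px$row[b] - half_window):(px$row[b] + half_window - 1L)
      cc <- (px$col[b] - half_window):(px$col[b] + half_window - 1L)
      blocks[, , , b] <- stack$frames[rr, cc, seq_len(n_frames)]
    }
  }
  index <- data.frame(block = seq_len(nrow(px)), sample_id = px$sample_id,
                      row = px$row, col = px$col)
  structure(list(blocks = blocks, index = index, skipped = skipped),
            class = "block_set")
}

# One row per cross-section pixel of every sample.
cross_section_pixels <- function(samples) {
  if (nrow(samples) == 0)
    return(data.frame(sample_id = integer(0), row = integer(0),
                      col = integer(0)))
  pieces <- lapply(seq_len(nrow(samples)), function(k) {
    s <- samples[k, ]
    along <- s$start:s$end
    if (s$axis == "h")
      data.frame(sample_id = s$sample_id, row = s$line, col = along)
    else
      data.frame(sample_id = s$sample_id, row = along, col = s$line)
  })
  do.call(rbind, pieces)
}

#' @export
print.block_set <- function(x, ...) {
  d <- dim(x$blocks)
  cat(sprintf("<block_set> %d blocks of %dx%dx%d (%d border pixels skipped)\n",
              d[4], d[1], d[2], d[3], nrow(x$skipped)))
  invisible(x)
}
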