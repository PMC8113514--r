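#' Construct a video stack
#'
#' The raw input of the pipeline: an ordered set of grayscale frames with
#' acquisition metadata. Frames are stored as a 3-D numeric array indexed
#' `[row, col, frame]`; intensities must be finite and non-negative.
#' Integer-valued stacks (e.g. 16-bit camera counts) and unit-range float
#' stacks (as produced by [render_video()]) are both accepted.
#'
#' @param frames numeric 3-D array `[row, col, frame]`, values >= 0.
#' @param frame_rate_hz acquisition rate in frames per second (default 32.5,
#'   the nominal IVM camera rate).
#' @param pixel_size_um physical pixel pitch in micrometres (default 0.4,
#'   i.e. a 400x400 um field of view imaged at 1000x1000 px).
#' @param bit_depth nominal sensor bit depth (default 16).
#' @param kept_frames optional integer vector of original frame indices,
#'   recorded by [stabilize()] when frames have been dropped.
#' @return an object of class `video_stack`.
#' @seealso [read_stack()], [write_stack()], [compute_sad()]
#' @export
video_stack <- function(frames, frame_rate_hz = 32.5, pixel_size_um = 0.4,
                        bit_depth = 16L, kept_frames = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array indexed [row, col, frame]")
  if (dim(frames)[3] < 2L)
    stop("a video stack needs fewer than 2 frames: got ", dim(frames)[3],
         "; at least 2 frames are required")
  if (!all(is.finite(frames)))
    stop("all intensities must be finite")
  if (min(frames) < 0)
    stop("all intensities must be >= 0")
  stopifnot(frame_rate_hz > 0, pixel_size_um > 0)
  structure(
    list(frames = frames,
         frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth),
         kept_frames = if (is.null(kept_frames)) seq_len(dim(frames)[3])
                       else as.integer(kept_frames)),
    class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d frames of %dx%d px, %g fps, %g um/px, %d bit\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Natural-sort order of file names
#'
#' Orders `frame_2` before `frame_10`, matching common microscope exporters.
#' @noRd
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)[[1]]
    if (m[1] == -1) return(s)
    parts <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    padded <- formatC(parts, width = 12, flag = "0")
    regmatches(s, gregexpr("[0-9]+", s)) <- list(padded)
    s
  }, character(1), USE.NAMES = FALSE)
  order(keys, x)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    stop("unsupported frame format: ", path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1] # first channel of RGB(A)
  img
}

#' Read a video stack from disk
#'
#' Accepts either a multipage TIFF or a directory of identically sized
#' single-frame images (TIFF or PNG). Directory entries are ordered by
#' natural sort of their file names, so `frame_2` precedes `frame_10`.
#' TIFF data are returned at their native integer scale; PNG frames are
#' returned in `[0, 1]` as read.
#'
#' @param path a multipage TIFF file or a directory of frames.
#' @param frame_rate_hz,pixel_size_um metadata defaults used when the file
#'   carries none.
#' @return a [video_stack()].
#' @export
read_stack <- function(path, frame_rate_hz = 32.5, pixel_size_um = 0.4) {
  if (!file.exists(path))
    stop("path does not exist: ", path)
  bit_depth <- 16L
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) < 2L)
      stop("fewer than 2 frames found in ", path)
    files <- files[natural_order(basename(files))]
    imgs <- lapply(files, read_frame_file)
    shapes <- vapply(imgs, function(m) dim(m)[1:2], integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("frames of mismatched shape in ", path)
    frames <- array(unlist(imgs, use.names = FALSE),
                    dim = c(shapes[1, 1], shapes[2, 1], length(imgs)))
    if (tolower(tools::file_ext(files[1])) == "png") bit_depth <- 8L
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("fewer than 2 frames in ", path)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits)) bit_depth <- as.integer(bits)
    pages <- lapply(pages, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
    shapes <- vapply(pages, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("frames of mismatched shape in ", path)
    frames <- array(unlist(pages, use.names = FALSE),
                    dim = c(shapes[1, 1], shapes[2, 1], length(pages)))
  }
  mode(frames) <- "numeric"
  video_stack(frames, frame_rate_hz = frame_rate_hz,
              pixel_size_um = pixel_size_um, bit_depth = bit_depth)
}

#' Write a video stack to disk
#'
#' Writes a multipage TIFF at the stack's bit depth. Integer-valued stacks
#' round-trip bit-exactly through [read_stack()]; float stacks in `[0, 1]`
#' are quantized to the stack's bit depth.
#'
#' @param stack a [video_stack()].
#' @param path output file; its directory must exist and be writable.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "video_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("destination not writable: ", path)
  scale <- 2^stack$bit_depth - 1
  fr <- stack$frames
  if (max(fr) > 1) fr <- fr / scale # integer counts -> unit range
  else fr <- round(fr * scale) / scale # quantize floats to bit depth
  fr <- pmin(pmax(fr, 0), 1)
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Write intersection labels to CSV
#'
#' One row per vessel/reference-line intersection: video id, the sample id,
#' grid line (axis + index), the intersection center, cross-section size and
#' the binary flow label. UTF-8 CSV with a header, so label sets are
#' diff-able and language-neutral.
#'
#' @param samples a data frame of intersection samples as produced by
#'   [find_intersections()], carrying a logical `label` column with no
#'   missing values.
#' @param path output CSV path.
#' @param video_id identifier recorded in the `video_id` column.
#' @export
write_labels <- function(samples, path, video_id = "video") {
  stopifnot(is.data.frame(samples))
  if (is.null(samples$label) || anyNA(samples$label))
    stop("every sample must carry a binary label")
  out <- data.frame(video_id = video_id,
                    sample_id = samples$sample_id,
                    axis = samples$axis,
                    line = samples$line,
                    center_row = samples$center_row,
                    center_col = samples$center_col,
                    n_pixels = samples$n_pixels,
                    label = as.integer(samples$label))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read intersection labels written by [write_labels()]
#'
#' @param path CSV path.
#' @return a data frame with a logical `label` column.
#' @export
read_labels <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$label <- as.logical(out$label)
  out
}
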