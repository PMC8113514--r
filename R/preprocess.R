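#' Estimate global frame motion by block matching
#'
#' Every frame is matched against the first frame with a traditional block
#' matching algorithm: blocks tiled with 50% overlap, an exhaustive integer
#' search in `+/- search_radius`, mean absolute difference as the match
#' score, and the per-frame global displacement taken as the median of the
#' per-block best matches. The median makes the estimate robust to local
#' RBC motion, which must not count as tissue motion. The per-frame motion
#' velocity is the frame-to-frame change in displacement times the frame
#' rate (px/s).
#'
#' @param stack a [video_stack()].
#' @param block_size matching block edge in px (default 32).
#' @param search_radius integer search range in px (default 8).
#' @param stride block tiling step; defaults to `block_size / 2`
#'   (50% overlap).
#' @return a data frame of class `motion_estimate` with columns `frame`,
#'   `drow`, `dcol` (displacement relative to frame 1) and
#'   `velocity_px_per_s`.
#' @export
estimate_motion <- function(stack, block_size = 32L, search_radius = 8L,
                            stride = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  if (block_size > d[1] || block_size > d[2])
    stop("frame smaller than block_size")
  if (is.null(stride)) stride <- max(1L, block_size %/% 2L)
  disp <- bm_motion_cpp(stack$frames, as.integer(block_size),
                        as.integer(search_radius), as.integer(stride))
  step <- sqrt(diff(disp[, 1])^2 + diff(disp[, 2])^2)
  out <- data.frame(frame = seq_len(d[3]),
                    drow = disp[, 1], dcol = disp[, 2],
                    velocity_px_per_s = c(0, step * stack$frame_rate_hz))
  attr(out, "block_size") <- block_size
  attr(out, "search_radius") <- search_radius
  class(out) <- c("motion_estimate", "data.frame")
  out
}

#' Reject frames with excessive tissue motion
#'
#' Removes every frame whose motion velocity exceeds the threshold
#' (default 0.3 px/s), keeping the surviving frames in their original
#' order. Frame 1, the motion reference, is always retained. The indices
#' of the surviving frames are recorded on the returned stack and travel
#' with it into [compute_sad()].
#'
#' @param stack a [video_stack()].
#' @param motion the [estimate_motion()] result for this stack.
#' @param velocity_threshold_px_per_s rejection threshold in px/s.
#' @return the sub-stack of surviving frames.
#' @export
stabilize <- function(stack, motion, velocity_threshold_px_per_s = 0.3) {
  stopifnot(inherits(stack, "video_stack"),
            inherits(motion, "motion_estimate"),
            nrow(motion) == dim(stack$frames)[3])
  keep <- motion$velocity_px_per_s <= velocity_threshold_px_per_s
  keep[1] <- TRUE
  if (sum(keep) < 2)
    stop("fewer than 2 frames survive the motion gate; ",
         "increase velocity_threshold_px_per_s")
  video_stack(stack$frames[, , keep, drop = FALSE],
              frame_rate_hz = stack$frame_rate_hz,
              pixel_size_um = stack$pixel_size_um,
              bit_depth = stack$bit_depth,
              kept_frames = stack$kept_frames[keep])
}

#' Temporal sum-of-absolute-differences image
#'
#' Collects, per pixel, the absolute intensity differences between
#' consecutive frames over the whole recording:
#' `SAD[r, c] = sum_i |frame_i[r, c] - frame_(i-1)[r, c]|`.
#' Pixels traversed by moving red blood cells flicker and accumulate large
#' values; static tissue accumulates only noise, so the SAD image is the
#' perfusion-geometry image of the recording. Arithmetic is in double
#' precision, so unsigned camera counts cannot wrap around. When the stack
#' has been through [stabilize()], differences across a splice are taken
#' between the two surviving neighbor frames.
#'
#' @param stack a [video_stack()] (at least 2 frames).
#' @return an object of class `sad_image`: `values` (H x W, >= 0),
#'   `n_frames_used`, `kept_frame_indices`.
#' @export
compute_sad <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  if (d[3] < 2) stop("n_frames < 2")
  vals <- rowSums(abs(stack$frames[, , -1, drop = FALSE] -
                      stack$frames[, , -d[3], drop = FALSE]), dims = 2)
  structure(list(values = vals,
                 n_frames_used = d[3],
                 kept_frame_indices = stack$kept_frames),
            class = "sad_image")
}

#' @export
print.sad_image <- function(x, ...) {
  cat(sprintf("<sad_image> %dx%d px from %d frames, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$n_frames_used,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization of a SAD image
#'
#' Rescales the SAD image to the unit range and applies standard CLAHE,
#' enhancing faint vessel structures ahead of ridge detection. The clip
#' limit is expressed as a fraction of the per-tile histogram mass
#' (0.01 by default, i.e. 2.56x the mean bin content at 256 bins).
#'
#' @param sad a [compute_sad()] result.
#' @param clip_limit clip limit as a fraction of per-tile histogram mass.
#' @param tile_grid number of tiles per axis, scalar or `c(nx, ny)`.
#' @param bins histogram bins.
#' @return a `sad_image` with values in `[0, 1]`.
#' @export
enhance_clahe <- function(sad, clip_limit = 0.01, tile_grid = 8L,
                          bins = 256L) {
  stopifnot(inherits(sad, "sad_image"))
  if (clip_limit <= 0) stop("clip limit must be positive")
  if (length(tile_grid) == 1L) tile_grid <- rep(tile_grid, 2L)
  v <- sad$values
  if (!all(is.finite(v))) stop("SAD values must be finite")
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  else v <- array(0, dim = dim(v))
  # EBImage's CLAHE needs tile sizes that divide the image; pad by
  # replication and crop back.
  H <- nrow(v); W <- ncol(v)
  Hp <- ceiling(H / (2 * tile_grid[1])) * 2 * tile_grid[1]
  Wp <- ceiling(W / (2 * tile_grid[2])) * 2 * tile_grid[2]
  vp <- v[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W))]
  eq <- EBImage::clahe(EBImage::Image(vp), nx = tile_grid[1],
                       ny = tile_grid[2], bins = bins,
                       limit = max(clip_limit * bins, 1))
  out <- EBImage::imageData(eq)[seq_len(H), seq_len(W)]
  out <- pmin(pmax(out, 0), 1)
  structure(list(values = out,
                 n_frames_used = sad$n_frames_used,
                 kept_frame_indices = sad$kept_frame_indices),
            class = "sad_image")
}
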