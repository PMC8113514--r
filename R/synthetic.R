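#' Phantom generator settings
#'
#' Configuration for the synthetic IVM phantom: transilluminated tissue in
#' which perfused vessels appear as bright-field tubes carrying moving dark
#' blobs (red blood cells absorb light) and non-perfused vessels as static
#' dark tubes (a stagnant RBC column). The defaults describe a desk-scale
#' recording: a 256x256 px field at 32.5 frames/s.
#'
#' Noise has three components, each switchable to zero: additive Gaussian
#' sensor noise (`noise_sigma`), a shot-noise approximation with
#' intensity-proportional standard deviation (`shot_sigma * sqrt(I)`), and
#' low-amplitude temporal flicker confined to stagnant-RBC tubes
#' (`static_jitter_sd`), emulating the Brownian jiggle of a stagnant cell
#' column that makes non-flowing vessels faintly visible in SAD images.
#'
#' @param shape image size `c(rows, cols)` in px.
#' @param n_vessels integer range `c(min, max)` of vessels per phantom.
#' @param width_range vessel diameter range in px.
#' @param flowing_fraction probability that a vessel is perfused.
#' @param speed_range RBC advection speed range, px/frame, for flowing
#'   vessels.
#' @param density_range RBC linear packing fraction range in `(0, 1]`.
#' @param contrast_range absorption contrast range in `(0, 1]`.
#' @param background background intensity on the unit scale.
#' @param noise_sigma additive Gaussian sensor noise sd (unit scale).
#' @param shot_sigma shot-noise coefficient; per-pixel sd is
#'   `shot_sigma * sqrt(intensity)`.
#' @param static_jitter_sd flicker sd inside non-flowing tubes (unit scale).
#' @param drift_px_per_s global tissue drift speed, px/s, applied as a
#'   sub-pixel translation of every frame.
#' @param min_separation minimum distance between vessel centerlines, px.
#' @param n_artifacts number of static dark artifact spots.
#' @param n_lines_per_axis reference-grid lines per axis used for the
#'   ground-truth intersection labels.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(256L, 256L),
                           n_vessels = c(8L, 12L),
                           width_range = c(3, 6),
                           flowing_fraction = 0.6,
                           speed_range = c(0.5, 3),
                           density_range = c(0.3, 0.7),
                           contrast_range = c(0.25, 0.45),
                           background = 0.85,
                           noise_sigma = 0.01,
                           shot_sigma = 0,
                           static_jitter_sd = 0.05,
                           drift_px_per_s = 0,
                           min_separation = 12,
                           n_artifacts = 3L,
                           n_lines_per_axis = 3L) {
  cfg <- list(shape = as.integer(shape), n_vessels = as.integer(n_vessels),
              width_range = width_range, flowing_fraction = flowing_fraction,
              speed_range = speed_range, density_range = density_range,
              contrast_range = contrast_range, background = background,
              noise_sigma = noise_sigma, shot_sigma = shot_sigma,
              static_jitter_sd = static_jitter_sd,
              drift_px_per_s = drift_px_per_s,
              min_separation = min_separation,
              n_artifacts = as.integer(n_artifacts),
              n_lines_per_axis = as.integer(n_lines_per_axis))
  if (max(cfg$width_range) >= min(cfg$shape))
    stop("impossible config: vessel width >= image size")
  stopifnot(flowing_fraction >= 0, flowing_fraction <= 1,
            all(cfg$n_vessels >= 1), cfg$n_vessels[1] <= cfg$n_vessels[2])
  class(cfg) <- "phantom_config"
  cfg
}

# Dense, arclength-resampled smooth curve through jittered waypoints.
smooth_centerline <- function(shape, margin, step = 0.5) {
  H <- shape[1]; W <- shape[2]
  p <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
  theta <- runif(1, 0, 2 * pi)
  n_way <- sample(4:6, 1)
  seg <- runif(n_way - 1, 0.18, 0.35) * min(H, W)
  pts <- matrix(NA_real_, n_way, 2)
  pts[1, ] <- p
  for (k in 2:n_way) {
    theta <- theta + runif(1, -0.6, 0.6)
    pts[k, ] <- pts[k - 1, ] + seg[k - 1] * c(sin(theta), cos(theta))
  }
  pts[, 1] <- pmin(pmax(pts[, 1], margin), H - margin)
  pts[, 2] <- pmin(pmax(pts[, 2], margin), W - margin)
  # spline through waypoints, parameterized by cumulative chord length
  d <- sqrt(rowSums(diff(pts)^2))
  u <- c(0, cumsum(pmax(d, 1e-6)))
  uu <- seq(0, u[n_way], by = 1)
  r <- spline(u, pts[, 1], xout = uu, method = "natural")$y
  c_ <- spline(u, pts[, 2], xout = uu, method = "natural")$y
  r <- pmin(pmax(r, margin), H - margin)
  c_ <- pmin(pmax(c_, margin), W - margin)
  # resample at constant arclength step
  dd <- sqrt(diff(r)^2 + diff(c_)^2)
  ss <- c(0, cumsum(dd))
  s_out <- seq(0, max(ss), by = step)
  list(row = approx(ss, r, xout = s_out, ties = "ordered")$y,
       col = approx(ss, c_, xout = s_out, ties = "ordered")$y,
       s = s_out)
}

#' Sample a random vessel tree
#'
#' Draws smooth random vessel centerlines (natural splines through jittered
#' waypoints, resampled at 0.5 px arclength steps) with per-vessel width,
#' contrast, RBC density and a flow label drawn with the configured flowing
#' fraction. Vessels are rejected and resampled when their centerline comes
#' closer than `min_separation` px to an existing one, so phantom vessels
#' stay resolvable.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; a fixed seed reproduces the identical tree.
#' @return a list of vessel specifications, each with fields `centerline`
#'   (data frame `row`, `col`, `s`), `width_px`, `flowing`,
#'   `rbc_speed_px_per_frame`, `rbc_density`, `contrast`.
#' @export
sample_vessel_tree <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  n <- if (config$n_vessels[1] == config$n_vessels[2]) config$n_vessels[1]
       else sample(config$n_vessels[1]:config$n_vessels[2], 1)
  vessels <- list()
  tries <- 0
  occupied_r <- numeric(0); occupied_c <- numeric(0)
  while (length(vessels) < n && tries < 80 * n) {
    tries <- tries + 1
    width <- runif(1, config$width_range[1], config$width_range[2])
    cl <- smooth_centerline(config$shape, margin = width + 2)
    if (length(occupied_r)) {
      sub <- seq(1, length(cl$row), by = 4)
      dmin <- min(vapply(sub, function(i) {
        min(sqrt((occupied_r - cl$row[i])^2 + (occupied_c - cl$col[i])^2))
      }, numeric(1)))
      if (dmin < config$min_separation) next
    }
    flowing <- runif(1) < config$flowing_fraction
    vessels[[length(vessels) + 1]] <- list(
      centerline = data.frame(row = cl$row, col = cl$col, s = cl$s),
      width_px = width,
      flowing = flowing,
      rbc_speed_px_per_frame = if (flowing)
        runif(1, config$speed_range[1], config$speed_range[2]) else 0,
      rbc_density = runif(1, config$density_range[1], config$density_range[2]),
      contrast = runif(1, config$contrast_range[1], config$contrast_range[2]))
    sub <- seq(1, length(cl$row), by = 4)
    occupied_r <- c(occupied_r, cl$row[sub])
    occupied_c <- c(occupied_c, cl$col[sub])
  }
  if (length(vessels) < n)
    warning("placed only ", length(vessels), " of ", n,
            " vessels under the separation constraint")
  vessels
}

# Rasterize tube masks, per-pixel ownership (nearest centerline wins) and
# the static absorption image: per vessel, a Gaussian cross-profile of the
# distance to its own centerline, scaled by its contrast (30% of it for
# perfused vessels, whose dark content is mostly the moving blobs).
rasterize_vessels <- function(vessels, shape) {
  H <- shape[1]; W <- shape[2]
  dist <- matrix(Inf, H, W)
  owner <- matrix(0L, H, W)
  radius <- matrix(0, H, W)
  absorb <- matrix(0, H, W)
  for (v in seq_along(vessels)) {
    ves <- vessels[[v]]
    cl <- ves$centerline
    w2 <- ves$width_px / 2
    sigma_t <- ves$width_px / 3
    amp <- ves$contrast * (if (ves$flowing) 0.3 else 1)
    rad <- max(ceiling(w2), ceiling(2.5 * sigma_t))
    for (i in seq(1, nrow(cl), by = 2)) { # 1 px steps along the line
      r0 <- cl$row[i]; c0 <- cl$col[i]
      rr <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
      cc <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
      d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
      absorb[rr, cc] <- pmax(absorb[rr, cc],
                             amp * exp(-d^2 / (2 * sigma_t^2)))
      upd <- d < dist[rr, cc] & d <= w2
      if (any(upd)) {
        block_d <- dist[rr, cc]; block_o <- owner[rr, cc]; block_w <- radius[rr, cc]
        block_d[upd] <- d[upd]; block_o[upd] <- v; block_w[upd] <- w2
        dist[rr, cc] <- block_d; owner[rr, cc] <- block_o; radius[rr, cc] <- block_w
      }
    }
  }
  inside <- dist <= radius
  owner[!inside] <- 0L
  list(dist = dist, owner = owner, tube = inside, absorb = absorb)
}

# Ground-truth intersection table: runs of the true tube mask along the
# default reference grid, labeled by the owning vessel's flow status.
truth_intersections <- function(raster, vessels, grid) {
  rows <- list()
  add_runs <- function(vals, owners, axis, line) {
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      own <- owners[idx]
      vid <- as.integer(names(which.max(table(own[own > 0]))))
      if (length(vid) == 0) next
      center <- idx[ceiling(length(idx) / 2)]
      rows[[length(rows) + 1]] <<- data.frame(
        axis = axis, line = line, start = starts[k], end = ends[k],
        center_row = if (axis == "h") line else center,
        center_col = if (axis == "h") center else line,
        vessel_id = vid, flowing = vessels[[vid]]$flowing)
    }
  }
  for (r in grid$rows) add_runs(raster$tube[r, ], raster$owner[r, ], "h", r)
  for (c_ in grid$cols) add_runs(raster$tube[, c_], raster$owner[, c_], "v", c_)
  if (length(rows) == 0)
    return(data.frame(axis = character(0), line = integer(0),
                      start = integer(0), end = integer(0),
                      center_row = integer(0), center_col = integer(0),
                      vessel_id = integer(0), flowing = logical(0)))
  do.call(rbind, rows)
}

# Sub-pixel translation by bilinear interpolation, replicate border.
translate_bilinear <- function(img, drow, dcol) {
  if (drow == 0 && dcol == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  r <- seq_len(H) - drow
  c_ <- seq_len(W) - dcol
  r0 <- pmin(pmax(floor(r), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(c_), 1), W); c1 <- pmin(c0 + 1, W)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c_ - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       img[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Render a phantom IVM video with ground truth
#'
#' Renders the vessel tree over a bright background. Perfused vessels carry
#' dark Gaussian-profiled blobs (2-6 px long, exponential gap spacing
#' scaled by the RBC density) advected along the centerline at the vessel's
#' speed, on top of a faint static plasma tube; non-perfused vessels are
#' static dark tubes, optionally with low-amplitude stagnant-column
#' flicker. Sensor noise, shot noise and global drift follow the config.
#' Blob contributions are clipped to the rasterized tube so that, with all
#' noise terms zero, temporal intensity changes occur only inside perfused
#' tubes.
#'
#' @param vessels vessel list from [sample_vessel_tree()].
#' @param n_frames number of frames (>= 2).
#' @param config the [phantom_config()] used for the tree.
#' @param seed integer seed for blob placement and noise.
#' @return a list with elements `stack` (a [video_stack()] in `[0, 1]`) and
#'   `truth` (class `phantom_truth`: the vessel list, per-pixel tube/owner
#'   rasters, and the ground-truth intersection table against the default
#'   reference grid).
#' @export
render_video <- function(vessels, n_frames = 200L, config = phantom_config(),
                         seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_frames < 2) stop("n_frames < 2")
  set.seed(seed + 1L)
  H <- config$shape[1]; W <- config$shape[2]
  raster <- rasterize_vessels(vessels, config$shape)

  base <- matrix(config$background, H, W)
  # static artifact spots (dark, irregular): invisible in SAD, visible in situ
  if (config$n_artifacts > 0) {
    for (k in seq_len(config$n_artifacts)) {
      ar <- runif(1, 8, H - 8); ac <- runif(1, 8, W - 8)
      sig <- runif(1, 1.5, 4); amp <- runif(1, 0.1, 0.3)
      rr <- max(1, floor(ar - 3 * sig)):min(H, ceiling(ar + 3 * sig))
      cc <- max(1, floor(ac - 3 * sig)):min(W, ceiling(ac + 3 * sig))
      base[rr, cc] <- base[rr, cc] -
        amp * exp(-outer((rr - ar)^2, (cc - ac)^2, "+") / (2 * sig^2))
    }
  }
  # static tube component (per-vessel Gaussian cross-profiles)
  base <- pmax(base - raster$absorb, 0.02)

  # blob trains for flowing vessels
  blob_sets <- lapply(seq_along(vessels), function(v) {
    ves <- vessels[[v]]
    if (!ves$flowing) return(NULL)
    L <- max(ves$centerline$s)
    mean_len <- 4
    mean_gap <- mean_len * (1 / ves$rbc_density - 1) + 0.5
    s <- numeric(0); pos <- runif(1, 0, mean_gap)
    while (pos < L) {
      s <- c(s, pos)
      pos <- pos + runif(1, 2, 6) + rexp(1, 1 / mean_gap)
    }
    if (length(s) == 0) s <- runif(1, 0, L)
    list(s0 = s, len = runif(length(s), 2, 6), L = L)
  })

  frames <- array(0, dim = c(H, W, n_frames))
  jitter_on <- config$static_jitter_sd > 0
  static_tube <- NULL
  if (jitter_on) {
    static_ids <- which(!vapply(vessels, `[[`, logical(1), "flowing"))
    static_tube <- raster$tube & (raster$owner %in% static_ids)
    dim(static_tube) <- dim(raster$tube)
    jitter_idx <- which(static_tube)
  }
  drift_per_frame <- config$drift_px_per_s / 32.5

  for (t in seq_len(n_frames)) {
    fr <- base
    occ <- NULL # contrast-weighted RBC occupancy, max over blobs:
                # absorption saturates, overlapping cells do not stack
    for (v in seq_along(vessels)) {
      bs <- blob_sets[[v]]
      if (is.null(bs)) next
      if (is.null(occ)) occ <- matrix(0, H, W)
      ves <- vessels[[v]]
      cl <- ves$centerline
      speed <- ves$rbc_speed_px_per_frame
      w2 <- ves$width_px / 2
      sp <- ves$width_px / 3
      s_now <- (bs$s0 + speed * (t - 1)) %% bs$L
      for (bi in seq_along(s_now)) {
        i <- max(1, min(length(cl$s), round(s_now[bi] / 0.5) + 1))
        r0 <- cl$row[i]; c0 <- cl$col[i]
        i2 <- min(length(cl$s), i + 2)
        i1 <- max(1, i - 2)
        tang <- c(cl$row[i2] - cl$row[i1], cl$col[i2] - cl$col[i1])
        nt <- sqrt(sum(tang^2)); if (nt < 1e-9) tang <- c(1, 0) else tang <- tang / nt
        sl <- bs$len[bi] / 3
        rad <- ceiling(max(2.5 * sl, w2))
        rr <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
        cc <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
        dr <- outer(rr - r0, rep(1, length(cc)))
        dc <- outer(rep(1, length(rr)), cc - c0)
        u <- dr * tang[1] + dc * tang[2]
        vv <- -dr * tang[2] + dc * tang[1]
        amp <- ves$contrast *
          exp(-(u^2 / (2 * sl^2) + vv^2 / (2 * sp^2)))
        amp[abs(vv) > w2] <- 0 # clip to the tube
        amp[!raster$tube[rr, cc]] <- 0
        occ[rr, cc] <- pmax(occ[rr, cc], amp)
      }
    }
    if (!is.null(occ)) fr <- fr - occ
    if (jitter_on && length(jitter_idx))
      fr[jitter_idx] <- fr[jitter_idx] +
        rnorm(length(jitter_idx), 0, config$static_jitter_sd)
    if (drift_per_frame != 0) {
      off <- drift_per_frame * (t - 1)
      fr <- translate_bilinear(fr, off, off * 0.5)
    }
    if (config$noise_sigma > 0)
      fr <- fr + rnorm(H * W, 0, config$noise_sigma)
    if (config$shot_sigma > 0)
      fr <- fr + rnorm(H * W, 0, config$shot_sigma) * sqrt(pmax(fr, 0))
    frames[, , t] <- pmin(pmax(fr, 0), 1)
  }

  grid <- build_grid(config$shape, config$n_lines_per_axis)
  truth <- structure(
    list(vessels = vessels, tube = raster$tube, owner = raster$owner,
         grid = grid,
         intersections = truth_intersections(raster, vessels, grid)),
    class = "phantom_truth")
  list(stack = video_stack(frames, frame_rate_hz = 32.5,
                           pixel_size_um = 0.4, bit_depth = 16L),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d vessels (%d flowing), %d grid crossings\n",
              length(x$vessels),
              sum(vapply(x$vessels, `[[`, logical(1), "flowing")),
              nrow(x$intersections)))
  invisible(x)
}
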