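# Step 1: curvilinear vessel segmentation on the enhanced SAD image,
# in the style of Steger's unbiased detector of curvilinear structures:
# Gaussian-derivative filtering, Hessian eigen-analysis, sub-pixel line
# point extraction with hysteresis thresholding.

# Separable Gaussian-derivative filtering with replicate borders.
# order 0, 1, 2 per axis; returns the filtered image.
gauss_deriv <- function(img, sigma, order_row = 0L, order_col = 0L) {
  m <- ceiling(3.5 * sigma)
  x <- seq(-m, m)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  kern <- function(order) {
    if (order == 0L) return(g)
    if (order == 1L) {
      k <- x / sigma^2 * g # correlation kernel for d/dx
      return(k / sum(x * k)) # exact unit response to a ramp
    }
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k) # exact zero response to constants
    2 * k / sum(x^2 * k) # exact response 2 to x^2
  }
  pass <- function(im, k, along_rows) {
    H <- nrow(im); W <- ncol(im)
    out <- matrix(0, H, W)
    for (s in seq_along(x)) {
      off <- x[s]
      if (along_rows) {
        idx <- pmin(pmax(seq_len(H) + off, 1), H)
        out <- out + k[s] * im[idx, , drop = FALSE]
      } else {
        idx <- pmin(pmax(seq_len(W) + off, 1), W)
        out <- out + k[s] * im[, idx, drop = FALSE]
      }
    }
    out
  }
  pass(pass(img, kern(order_col), FALSE), kern(order_row), TRUE)
}

#' Detect curvilinear ridge points (Steger-style)
#'
#' Identifies pixels with vessel-like ridge geometry in the enhanced SAD
#' image by examining the degree and direction of intensity change.
#' Gaussian-derivative filters at scale `sigma` give the gradient and
#' Hessian at every pixel; the ridge normal is the Hessian eigenvector of
#' the largest-magnitude eigenvalue. A pixel emits a ridge point when the
#' first directional derivative along the normal vanishes inside the pixel
#' (second-order Taylor zero within half a pixel of the center) and the
#' eigenvalue is negative (a bright line on the SAD image) with magnitude
#' at or above the low threshold. Hysteresis keeps low-threshold points
#' only when their 8-connected candidate component also contains a point
#' at or above the high threshold.
#'
#' Thresholds are given as quantiles of the ridge-strength distribution
#' (the negative-eigenvalue magnitudes) because the dynamic range of SAD
#' images varies between recordings; absolute thresholds may be supplied
#' instead.
#'
#' @param image a `sad_image` (normally CLAHE-enhanced) or a plain matrix.
#' @param sigma Gaussian scale in px; the default follows the width-scale
#'   relation `sigma = w / (2 * sqrt(3))` for the expected vessel width
#'   `width_px`.
#' @param width_px expected vessel width in px (default 4), used only to
#'   derive `sigma` when `sigma` is `NULL`.
#' @param low_q,high_q strength quantiles for hysteresis (defaults 0.90 and
#'   0.97).
#' @param low_thresh,high_thresh absolute strength thresholds; when given
#'   they override the quantiles.
#' @return a data frame of class `ridge_points`: sub-pixel `row`, `col`,
#'   the emitting pixel (`pixel_row`, `pixel_col`), the unit ridge normal
#'   (`normal_row`, `normal_col`) and `strength` (the magnitude of the
#'   principal second directional derivative).
#' @export
steger_detect <- function(image, sigma = NULL, width_px = 4,
                          low_q = 0.90, high_q = 0.97,
                          low_thresh = NULL, high_thresh = NULL) {
  v <- if (inherits(image, "sad_image")) image$values else image
  stopifnot(is.matrix(v))
  if (is.null(sigma)) sigma <- width_px / (2 * sqrt(3))
  if (sigma <= 0) stop("sigma must be positive")
  H <- nrow(v); W <- ncol(v)

  gr <- gauss_deriv(v, sigma, 1L, 0L)
  gc <- gauss_deriv(v, sigma, 0L, 1L)
  hrr <- gauss_deriv(v, sigma, 2L, 0L)
  hcc <- gauss_deriv(v, sigma, 0L, 2L)
  hrc <- gauss_deriv(v, sigma, 1L, 1L)

  # closed-form eigen-decomposition of the 2x2 symmetric Hessian;
  # lambda1 is the eigenvalue of largest magnitude for bright ridges
  # (most negative second derivative across the line).
  half_tr <- (hrr + hcc) / 2
  disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
  lam <- half_tr - disc # smallest (most negative) eigenvalue
  # eigenvector for lam: (hrc, lam - hrr), or (lam - hcc, hrc); pick the
  # branch with the larger norm for numerical stability
  e1r <- hrc;        e1c <- lam - hrr
  e2r <- lam - hcc;  e2c <- hrc
  n1 <- e1r^2 + e1c^2
  n2 <- e2r^2 + e2c^2
  use2 <- n2 > n1
  nr <- ifelse(use2, e2r, e1r)
  nc <- ifelse(use2, e2c, e1c)
  nn <- sqrt(nr^2 + nc^2)
  degen <- nn < 1e-12 # isotropic point: pick an arbitrary unit normal
  nr[degen] <- 1; nc[degen] <- 0; nn[degen] <- 1
  nr <- nr / nn; nc <- nc / nn

  strength <- -lam
  strength[strength < 0] <- 0
  if (is.null(high_thresh) || is.null(low_thresh)) {
    if (all(strength == 0))
      return(empty_ridge_points())
    # quantiles of the full per-pixel strength distribution (zeros where
    # the eigenvalue is non-negative): robust to the per-video SAD range
    if (is.null(high_thresh))
      high_thresh <- quantile(strength, high_q, names = FALSE)
    if (is.null(low_thresh))
      low_thresh <- quantile(strength, low_q, names = FALSE)
    high_thresh <- max(high_thresh, 1e-12)
    low_thresh <- max(low_thresh, 1e-12)
  }
  if (low_thresh > high_thresh) low_thresh <- high_thresh

  denom <- nr^2 * hrr + 2 * nr * nc * hrc + nc^2 * hcc # = lam on ridges
  tt <- ifelse(abs(denom) > 1e-12, -(gr * nr + gc * nc) / denom, Inf)
  # isotropic half-pixel acceptance (|t| <= 0.5: the crest passes within
  # half a pixel of the center, whatever the line orientation), with a
  # hair of slack so a crest exactly between two pixel rows is claimed by
  # both neighbors instead of neither
  on_ridge <- lam < 0 & strength >= low_thresh & abs(tt) <= 0.5 + 1e-6
  if (!any(on_ridge)) return(empty_ridge_points())

  # hysteresis: keep candidate components containing a strong pixel
  labs <- label8_cpp(on_ridge)
  strong_labs <- unique(labs[on_ridge & strength >= high_thresh])
  keep <- on_ridge & (labs %in% strong_labs)
  dim(keep) <- dim(labs)
  if (!any(keep)) return(empty_ridge_points())

  idx <- which(keep)
  pr <- ((idx - 1) %% H) + 1
  pc <- ((idx - 1) %/% H) + 1
  out <- data.frame(row = pr + tt[idx] * nr[idx],
                    col = pc + tt[idx] * nc[idx],
                    pixel_row = pr, pixel_col = pc,
                    normal_row = nr[idx], normal_col = nc[idx],
                    strength = strength[idx])
  class(out) <- c("ridge_points", "data.frame")
  out
}

empty_ridge_points <- function() {
  out <- data.frame(row = numeric(0), col = numeric(0),
                    pixel_row = integer(0), pixel_col = integer(0),
                    normal_row = numeric(0), normal_col = numeric(0),
                    strength = numeric(0))
  class(out) <- c("ridge_points", "data.frame")
  out
}

#' Rasterize ridge points into a binary vessel map
#'
#' Each ridge point marks its containing pixel; the mask is the union.
#' Connected structures are labeled (8-connectivity) and their pixel
#' counts recorded.
#'
#' @param points a [steger_detect()] result.
#' @param shape image shape `c(rows, cols)`.
#' @return an object of class `vessel_map`: logical `mask`, integer
#'   `components` labeling, and `component_sizes`.
#' @export
link_and_binarize <- function(points, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(points) > 0) {
    stopifnot(all(points$pixel_row >= 1), all(points$pixel_row <= shape[1]),
              all(points$pixel_col >= 1), all(points$pixel_col <= shape[2]))
    mask[cbind(points$pixel_row, points$pixel_col)] <- TRUE
  }
  vessel_map(mask)
}

vessel_map <- function(mask) {
  comp <- label8_cpp(mask)
  sizes <- if (max(comp) > 0) tabulate(comp[comp > 0], nbins = max(comp))
           else integer(0)
  structure(list(mask = mask, components = comp, component_sizes = sizes),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %dx%d px, %d true pixels in %d components\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              length(x$component_sizes)))
  invisible(x)
}

#' Post-process a binary vessel map
#'
#' Fills discontinuities with a morphological close (disk structuring
#' element of radius `close_radius`; radius 1 is the full 3x3
#' neighborhood, sized to bridge 1-px gaps), then removes every
#' 8-connected component with fewer than `min_segment_px` pixels. The
#' operation is idempotent.
#'
#' @param map a [link_and_binarize()] result (or any `vessel_map`).
#' @param close_radius structuring-element radius in px (>= 0; 0 skips the
#'   close).
#' @param min_segment_px minimum component pixel count (strict `<` is
#'   removed; a 4-px component survives the default).
#' @return a cleaned `vessel_map`.
#' @export
postprocess_map <- function(map, close_radius = 1, min_segment_px = 4) {
  stopifnot(inherits(map, "vessel_map"))
  if (close_radius < 0) stop("close_radius must be >= 0")
  mask <- map$mask
  if (close_radius > 0 && any(mask)) {
    size <- 2 * close_radius + 1
    brush <- if (close_radius <= 1) matrix(1, size, size)
             else EBImage::makeBrush(size, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(mask * 1), brush)
    mask <- EBImage::imageData(closed) > 0.5
  }
  comp <- label8_cpp(mask)
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    small <- which(sizes < min_segment_px)
    if (length(small)) mask[comp %in% small] <- FALSE
    dim(mask) <- dim(comp)
  }
  vessel_map(mask)
}
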