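#' Pipeline configuration
#'
#' One configuration object covering every stage's tunables, with the
#' module defaults. Serializes to/from YAML via [write_pipeline_config()]
#' and [read_pipeline_config()]; unknown keys are rejected.
#'
#' @param velocity_threshold_px_per_s motion-gate threshold (px/s).
#' @param block_size,search_radius block-matching parameters.
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param width_px,low_q,high_q ridge-detector parameters.
#' @param close_radius,min_segment_px vessel-map post-processing.
#' @param n_lines_per_axis reference grid lines per axis.
#' @param half_window,n_frames data-block geometry.
#' @param cnn a [cnn_config()].
#' @param match_radius_px evaluation matching tolerance.
#' @param seed global seed; the CNN seed defaults to it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(velocity_threshold_px_per_s = 0.3,
                            block_size = 32L, search_radius = 8L,
                            clip_limit = 0.01, tile_grid = 8L,
                            width_px = 4, low_q = 0.90, high_q = 0.97,
                            close_radius = 1, min_segment_px = 4,
                            n_lines_per_axis = 3L,
                            half_window = 8L, n_frames = 200L,
                            cnn = NULL, match_radius_px = 3,
                            seed = 1L) {
  if (is.null(cnn)) cnn <- cnn_config(seed = seed)
  structure(list(velocity_threshold_px_per_s = velocity_threshold_px_per_s,
                 block_size = as.integer(block_size),
                 search_radius = as.integer(search_radius),
                 clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 width_px = width_px, low_q = low_q, high_q = high_q,
                 close_radius = close_radius,
                 min_segment_px = min_segment_px,
                 n_lines_per_axis = as.integer(n_lines_per_axis),
                 half_window = as.integer(half_window),
                 n_frames = as.integer(n_frames),
                 cnn = cnn, match_radius_px = match_radius_px,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$cnn <- unclass(lst$cnn)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cnn_lst <- lst$cnn
  lst$cnn <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cnn <- NULL
  if (!is.null(cnn_lst)) {
    cnn_known <- names(formals(cnn_config))
    extra <- setdiff(names(cnn_lst), c(cnn_known, "conv1", "conv2", "pool"))
    if (length(extra))
      stop("unknown cnn config keys: ", paste(extra, collapse = ", "))
    cnn <- do.call(cnn_config,
                   cnn_lst[intersect(names(cnn_lst), cnn_known)])
  }
  do.call(pipeline_config, c(lst, list(cnn = cnn)))
}

#' Run the two-step analysis pipeline
#'
#' Orchestrates preprocess (motion gate + SAD + CLAHE), step-1 segmentation
#' (ridge detection + binary map post-processing), reference-grid sampling,
#' block extraction and step-2 classification, returning one flow decision
#' per vessel/reference-line crossing. When `out_dir` is given, every
#' intermediate artifact is written there (`sad.tif`, `mask.png`,
#' `decisions.csv`, `motion.csv`, `run_log.yaml`, `overlay.png`).
#'
#' @param stack a [video_stack()] (the input file itself is never
#'   mutated).
#' @param model a trained `cnn_model` or `logistic_baseline`; when `NULL`,
#'   `train_blocks`/`train_labels` must be supplied and a CNN is trained
#'   first.
#' @param config a [pipeline_config()].
#' @param train_blocks,train_labels optional training data used when no
#'   model is given.
#' @param out_dir optional artifact directory.
#' @return a list of class `pipeline_result`: `decisions` (data frame with
#'   one row per crossing: sample id, center, `n_pixels`,
#'   `flowing_fraction`, `vessel_flowing`), plus `sad`, `enhanced`, `map`,
#'   `grid`, `samples`, `motion`, `model` and per-stage `counts`.
#' @export
run_pipeline <- function(stack, model = NULL, config = pipeline_config(),
                         train_blocks = NULL, train_labels = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(stack, "video_stack"),
            inherits(config, "pipeline_config"))
  if (is.null(model) && (is.null(train_blocks) || is.null(train_labels)))
    stop("no model provided; supply `model` or training data for ",
         "`train_cnn` (train_blocks + train_labels)")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  motion <- stage("estimate_motion",
                  estimate_motion(stack, config$block_size,
                                  config$search_radius))
  stable <- stage("stabilize",
                  stabilize(stack, motion,
                            config$velocity_threshold_px_per_s))
  sad <- stage("compute_sad", compute_sad(stable))
  enhanced <- stage("enhance_clahe",
                    enhance_clahe(sad, config$clip_limit, config$tile_grid))
  points <- stage("steger_detect",
                  steger_detect(enhanced, width_px = config$width_px,
                                low_q = config$low_q, high_q = config$high_q))
  map0 <- stage("link_and_binarize",
                link_and_binarize(points, dim(enhanced$values)))
  map <- stage("postprocess_map",
               postprocess_map(map0, config$close_radius,
                               config$min_segment_px))
  grid <- stage("build_grid",
                build_grid(dim(map$mask), config$n_lines_per_axis))
  samples <- stage("find_intersections", find_intersections(grid, map))
  blocks <- stage("extract_blocks",
                  extract_blocks(stable, samples, config$half_window,
                                 config$n_frames))

  if (is.null(model))
    model <- stage("train_cnn",
                   train_cnn(train_blocks, train_labels, config$cnn))

  probs <- if (dim(blocks$blocks)[4] > 0)
    stage("classify", predict(model, blocks)) else numeric(0)

  decisions <- do.call(rbind, lapply(seq_len(nrow(samples)), function(k) {
    s <- samples[k, ]
    p <- probs[blocks$index$sample_id == s$sample_id]
    if (length(p) == 0)
      return(data.frame(sample_id = s$sample_id, axis = s$axis,
                        line = s$line, center_row = s$center_row,
                        center_col = s$center_col, n_pixels = s$n_pixels,
                        n_classified = 0L, flowing_fraction = NA_real_,
                        vessel_flowing = FALSE))
    d <- decide_vessel(p, config$cnn$prob_threshold)
    data.frame(sample_id = s$sample_id, axis = s$axis, line = s$line,
               center_row = s$center_row, center_col = s$center_col,
               n_pixels = s$n_pixels, n_classified = length(p),
               flowing_fraction = d$flowing_fraction,
               vessel_flowing = d$vessel_flowing)
  }))
  if (is.null(decisions))
    decisions <- data.frame(sample_id = integer(0), axis = character(0),
                            line = integer(0), center_row = integer(0),
                            center_col = integer(0), n_pixels = integer(0),
                            n_classified = integer(0),
                            flowing_fraction = numeric(0),
                            vessel_flowing = logical(0))

  counts <- list(n_frames_in = dim(stack$frames)[3],
                 n_frames_kept = dim(stable$frames)[3],
                 n_frames_dropped = dim(stack$frames)[3] -
                                    dim(stable$frames)[3],
                 n_ridge_points = nrow(points),
                 n_segments_raw = length(map0$component_sizes),
                 n_segments_kept = length(map$component_sizes),
                 n_crossings = nrow(samples),
                 n_border_pixels_skipped = nrow(blocks$skipped))

  result <- structure(list(decisions = decisions, sad = sad,
                           enhanced = enhanced, map = map, grid = grid,
                           samples = samples, motion = motion,
                           model = model, counts = counts,
                           config = config),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sadn <- enhanced$values
    tiff::writeTIFF(sadn, file.path(out_dir, "sad.tif"),
                    bits.per.sample = 16)
    png::writePNG(map$mask * 1, file.path(out_dir, "mask.png"))
    write.csv(decisions, file.path(out_dir, "decisions.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(motion), file.path(out_dir, "motion.csv"),
              row.names = FALSE)
    yaml::write_yaml(counts, file.path(out_dir, "run_log.yaml"))
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    render_assessment(enhanced, decisions, grid,
                      file.path(out_dir, "overlay.png"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d crossings (%d flowing), ",
                     "%d/%d frames kept\n"),
              nrow(x$decisions), sum(x$decisions$vessel_flowing),
              x$counts$n_frames_kept, x$counts$n_frames_in))
  invisible(x)
}

#' Render the final assessment overlay
#'
#' Draws the reference grid over the (enhanced) SAD image and marks every
#' crossing: green for flowing, red for non-flowing — the pipeline's
#' analogue of the manual assessment image.
#'
#' @param sad a `sad_image` (or plain matrix in `[0, 1]`).
#' @param decisions the pipeline `decisions` data frame (needs
#'   `center_row`, `center_col`, `vessel_flowing`).
#' @param grid a `reference_grid` (optional; lines are drawn when given).
#' @param path optional PNG output path.
#' @return invisibly, the H x W x 3 RGB array.
#' @export
render_assessment <- function(sad, decisions, grid = NULL, path = NULL) {
  v <- if (inherits(sad, "sad_image")) sad$values else sad
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  H <- nrow(v); W <- ncol(v)
  rgb <- array(rep(v, 3), dim = c(H, W, 3))
  if (!is.null(grid)) {
    rgb[grid$rows, , 1] <- pmin(rgb[grid$rows, , 1] + 0.25, 1)
    rgb[grid$rows, , 2] <- pmin(rgb[grid$rows, , 2] + 0.25, 1)
    rgb[, grid$cols, 1] <- pmin(rgb[, grid$cols, 1] + 0.25, 1)
    rgb[, grid$cols, 2] <- pmin(rgb[, grid$cols, 2] + 0.25, 1)
  }
  mark <- function(r, c_, channel) {
    rr <- max(1, r - 2):min(H, r + 2)
    cc <- max(1, c_ - 2):min(W, c_ + 2)
    rgb[rr, cc, ] <<- 0
    rgb[rr, cc, channel] <<- 1
  }
  for (k in seq_len(nrow(decisions)))
    mark(decisions$center_row[k], decisions$center_col[k],
         if (decisions$vessel_flowing[k]) 2L else 1L)
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}
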