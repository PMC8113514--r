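#' Synthetic two-step benchmark
#'
#' Runs the complete study on generated phantoms: renders `n_videos` IVM
#' phantom videos with ground-truth flow labels, pushes each through
#' preprocessing (motion gate, SAD, CLAHE) and step-1 segmentation,
#' collects the labeled grid crossings and their data blocks, trains the
#' 3D-CNN and the logistic baseline on the training videos, and evaluates
#' both at the vessel level on the held-out test videos (videos are never
#' shared between splits). Also reports the end-to-end detection rate and
#' error rate of the full pipeline (with the trained CNN) against the
#' phantom ground truth on the test videos.
#'
#' The default problem size — 16 videos of 256 x 256 px and around 300
#' labeled crossings in total, 200-frame blocks, up to 12 training epochs —
#' is a desk-scale rendition of the original study (1000 x 1000 px videos,
#' tens of thousands of labeled points, 100 epochs).
#'
#' @param seed integer; seeds phantom generation, network initialization
#'   and batch shuffling.
#' @param n_videos number of phantom videos.
#' @param n_train_videos how many of them train the classifiers; the rest
#'   are the test split.
#' @param n_frames frames rendered per video (a small surplus over
#'   `block_frames` so the motion gate may drop a few).
#' @param block_frames temporal depth of the classifier blocks.
#' @param max_epochs training epoch cap for the 3D-CNN.
#' @param phantom a [phantom_config()].
#' @param pipeline a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return a list with vessel-level `cnn_accuracy`, `logistic_accuracy`,
#'   the corresponding [confusion_matrix()] objects, pooled end-to-end
#'   `detection_rate` and `error_rate`, `n_crossings` (labeled crossings
#'   over all videos), `n_blocks`, the trained models and the per-stage
#'   wall-clock `timings`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_videos = 16L,
                                n_train_videos = 12L, n_frames = 215L,
                                block_frames = 200L, max_epochs = 12L,
                                phantom = phantom_config(),
                                pipeline = NULL, verbose = FALSE) {
  stopifnot(n_train_videos < n_videos)
  if (is.null(pipeline))
    pipeline <- pipeline_config(seed = seed,
                                cnn = cnn_config(max_epochs = max_epochs,
                                                 seed = seed))
  t_all <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))

  prep_one <- function(v) {
    vseed <- (seed * 1000L + v) %% .Machine$integer.max
    ves <- sample_vessel_tree(phantom, seed = vseed)
    pv <- render_video(ves, n_frames = n_frames, phantom, seed = vseed)
    motion <- estimate_motion(pv$stack, pipeline$block_size,
                              pipeline$search_radius)
    stable <- stabilize(pv$stack, motion,
                        pipeline$velocity_threshold_px_per_s)
    sad <- enhance_clahe(compute_sad(stable), pipeline$clip_limit,
                         pipeline$tile_grid)
    pts <- steger_detect(sad, width_px = pipeline$width_px,
                         low_q = pipeline$low_q, high_q = pipeline$high_q)
    map <- postprocess_map(link_and_binarize(pts, dim(sad$values)),
                           pipeline$close_radius, pipeline$min_segment_px)
    grid <- build_grid(dim(map$mask), pipeline$n_lines_per_axis)
    samples <- label_crossings(find_intersections(grid, map), pv$truth,
                               pipeline$match_radius_px)
    blocks <- extract_blocks(stable, samples, pipeline$half_window,
                             block_frames)
    say("video %d: %d crossings (%d flowing), %d blocks", v,
        nrow(samples), sum(samples$label), dim(blocks$blocks)[4])
    list(samples = samples, blocks = blocks, truth = pv$truth)
  }

  t0 <- Sys.time()
  videos <- lapply(seq_len(n_videos), prep_one)
  t_prep <- as.numeric(Sys.time() - t0, units = "secs")

  gather <- function(ids) {
    bl <- lapply(videos[ids], function(x) x$blocks$blocks)
    nb <- vapply(bl, function(b) dim(b)[4], integer(1))
    win <- dim(bl[[1]])[1:3]
    idx <- do.call(rbind, lapply(seq_along(ids), function(i) {
      x <- videos[[ids[i]]]
      data.frame(video = ids[i],
                 sample_id = x$blocks$index$sample_id,
                 label = x$samples$label[match(x$blocks$index$sample_id,
                                               x$samples$sample_id)])
    }))
    list(blocks = array(unlist(bl), dim = c(win, sum(nb))), idx = idx)
  }
  train_ids <- seq_len(n_train_videos)
  test_ids <- setdiff(seq_len(n_videos), train_ids)
  tr <- gather(train_ids)
  te <- gather(test_ids)

  t0 <- Sys.time()
  cnn <- train_cnn(tr$blocks, tr$idx$label, pipeline$cnn, verbose = verbose)
  t_cnn <- as.numeric(Sys.time() - t0, units = "secs")
  t0 <- Sys.time()
  logit <- train_logistic_baseline(tr$blocks, tr$idx$label,
                                   seed = seed)
  t_logit <- as.numeric(Sys.time() - t0, units = "secs")

  # vessel-level decisions on the held-out videos
  vessel_eval <- function(probs) {
    pred <- logical(0); truth <- logical(0)
    for (i in seq_along(test_ids)) {
      x <- videos[[test_ids[i]]]
      rows <- te$idx$video == test_ids[i]
      for (sid in unique(te$idx$sample_id[rows])) {
        p <- probs[rows & te$idx$sample_id == sid]
        if (!length(p)) next
        pred <- c(pred, decide_vessel(p, pipeline$cnn$prob_threshold)$
                          vessel_flowing)
        truth <- c(truth, x$samples$label[x$samples$sample_id == sid])
      }
    }
    cm <- confusion(pred, truth)
    list(cm = cm, accuracy = metrics(cm)$accuracy)
  }
  p_cnn <- predict(cnn, te$blocks)
  p_log <- predict(logit, te$blocks)
  ev_cnn <- vessel_eval(p_cnn)
  ev_log <- vessel_eval(p_log)

  # pooled end-to-end detection/error of the CNN pipeline vs ground truth
  n_true <- n_det <- n_marked <- n_false <- 0L
  for (i in seq_along(test_ids)) {
    x <- videos[[test_ids[i]]]
    rows <- te$idx$video == test_ids[i]
    dec <- do.call(rbind, lapply(unique(x$samples$sample_id), function(sid) {
      p <- p_cnn[rows & te$idx$sample_id == sid]
      if (!length(p)) return(NULL)
      s <- x$samples[x$samples$sample_id == sid, ]
      data.frame(center_row = s$center_row, center_col = s$center_col,
                 vessel_flowing =
                   decide_vessel(p, pipeline$cnn$prob_threshold)$
                     vessel_flowing)
    }))
    if (is.null(dec)) next
    ev <- end_to_end_eval(dec, x$truth, pipeline$match_radius_px)
    n_true <- n_true + ev$n_true_flowing
    n_det <- n_det + ev$n_detected
    n_marked <- n_marked + ev$n_marked_flowing
    n_false <- n_false + ev$n_false_marks
  }

  list(cnn_accuracy = ev_cnn$accuracy,
       logistic_accuracy = ev_log$accuracy,
       cnn_confusion = ev_cnn$cm,
       logistic_confusion = ev_log$cm,
       detection_rate = if (n_true > 0) n_det / n_true else NA_real_,
       error_rate = if (n_marked > 0) n_false / n_marked else NA_real_,
       n_crossings = sum(vapply(videos, function(x) nrow(x$samples),
                                integer(1))),
       n_test_crossings = ev_cnn$cm$tp + ev_cnn$cm$tn + ev_cnn$cm$fp +
                          ev_cnn$cm$fn,
       n_blocks = dim(tr$blocks)[4] + dim(te$blocks)[4],
       cnn_model = cnn, logistic_model = logit,
       history = cnn$history,
       timings = list(prepare_s = t_prep, train_cnn_s = t_cnn,
                      train_logistic_s = t_logit,
                      total_s = as.numeric(Sys.time() - t_all,
                                           units = "secs")))
}
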