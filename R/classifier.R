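# Step 2: the spatio-temporal 3D-CNN that labels each cross-section pixel
# as flowing or not, the logistic-regression baseline, and the
# vessel-level majority rule.

#' 3D-CNN configuration
#'
#' The network consumes `16 x 16 x 200` data blocks and consists of two
#' hidden 3D convolution layers (eight 7x7x7 filters, then eight 5x5x5
#' filters, ReLU activations, valid stride-1 convolutions), a 2x2x2
#' max-pool, a flatten (length 6840 for the standard input), one 128-unit
#' ReLU hidden layer and a 2-way soft-max. Training minimizes the
#' categorical cross-entropy with Adadelta in batches of 30 for up to 100
#' epochs, stopping early once the epoch-to-epoch change in training loss
#' stays below `early_stop_tol` for `early_stop_patience` consecutive
#' epochs (the practical reading of "until the weights converge").
#'
#' @param mlp_hidden hidden-layer width of the MLP head.
#' @param prob_threshold per-pixel probability threshold (flow when
#'   `p >= prob_threshold`).
#' @param batch_size training batch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_tol,early_stop_patience early-stopping rule on the
#'   training loss.
#' @param adadelta_rho,adadelta_eps Adadelta decay and conditioning
#'   constants.
#' @param normalize whether blocks are min-max rescaled to `[0, 1]` per
#'   block before entering the network (see [normalize_block()]).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(mlp_hidden = 128L, prob_threshold = 0.5,
                       batch_size = 30L, max_epochs = 100L,
                       early_stop_tol = 1e-4, early_stop_patience = 3L,
                       adadelta_rho = 0.95, adadelta_eps = 1e-6,
                       normalize = TRUE, seed = 1L) {
  structure(list(conv1 = list(filters = 8L, kernel = c(7L, 7L, 7L)),
                 conv2 = list(filters = 8L, kernel = c(5L, 5L, 5L)),
                 pool = c(2L, 2L, 2L),
                 mlp_hidden = as.integer(mlp_hidden),
                 prob_threshold = prob_threshold,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = as.integer(early_stop_patience),
                 adadelta_rho = adadelta_rho,
                 adadelta_eps = adadelta_eps,
                 normalize = isTRUE(normalize),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer output shapes of the 3D-CNN
#'
#' Applies the valid stride-1 convolution and floor-division pooling
#' arithmetic to an input shape and returns the shape after every layer,
#' including the flattened length. For the standard `16 x 16 x 200` block
#' the flatten is exactly 6840 — the architecture's anchor.
#'
#' @param config a [cnn_config()].
#' @param input_shape `c(rows, cols, frames)` of one data block.
#' @return a named list: `input`, `conv1`, `conv2`, `pool`, `flatten`.
#' @export
layer_output_shapes <- function(config = cnn_config(),
                                input_shape = c(16L, 16L, 200L)) {
  k1 <- config$conv1$kernel; k2 <- config$conv2$kernel; p <- config$pool
  s1 <- input_shape - k1 + 1L
  if (any(s1 < 1)) stop("kernel larger than input")
  s2 <- s1 - k2 + 1L
  if (any(s2 < 1)) stop("kernel larger than conv1 output")
  s3 <- s2 %/% p
  if (any(s3 < 1)) stop("pooling window larger than conv2 output")
  list(input = input_shape,
       conv1 = c(s1, config$conv1$filters),
       conv2 = c(s2, config$conv2$filters),
       pool = c(s3, config$conv2$filters),
       flatten = prod(s3) * config$conv2$filters)
}

#' Normalize a data block to the unit range
#'
#' Per-block linear rescale `(x - min) / (max - min)`; a constant block
#' maps to all zeros. This is the normalization applied to every block
#' before it enters the network or the logistic baseline.
#'
#' @param block a numeric array.
#' @return the normalized array.
#' @export
normalize_block <- function(block) {
  if (!all(is.finite(block))) stop("block values must be finite")
  rng <- range(block)
  if (rng[2] > rng[1]) (block - rng[1]) / (rng[2] - rng[1])
  else array(0, dim = dim(block))
}

# He-uniform for the ReLU layers (limit sqrt(6/fan_in)), Glorot for the
# soft-max head; all draws from the config seed.
init_weights <- function(shapes, config) {
  set.seed(config$seed)
  unif <- function(nrow_, ncol_, lim) {
    matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
  }
  k1 <- prod(config$conv1$kernel)
  k2 <- prod(config$conv2$kernel) * config$conv1$filters
  f <- shapes$flatten
  h <- config$mlp_hidden
  list(W1 = unif(k1, config$conv1$filters, sqrt(6 / k1)),
       b1 = numeric(config$conv1$filters),
       W2 = unif(k2, config$conv2$filters, sqrt(6 / k2)),
       b2 = numeric(config$conv2$filters),
       Wh = unif(f, h, sqrt(6 / f)),
       bh = numeric(h),
       Wo = unif(h, 2L, sqrt(6 / (h + 2))),
       bo = numeric(2L))
}

block_array <- function(blocks) {
  if (inherits(blocks, "block_set")) blocks <- blocks$blocks
  stopifnot(is.array(blocks), length(dim(blocks)) == 4L)
  blocks
}

#' Train the 3D-CNN flow classifier
#'
#' Trains the network of [cnn_config()] on labeled data blocks with
#' Adadelta on the categorical cross-entropy. All randomness (Glorot
#' weight initialization, batch shuffling) is seeded from the config seed,
#' so runs are reproducible on one platform.
#'
#' @param blocks a [extract_blocks()] result or a raw array
#'   `[rows, cols, frames, n]`.
#' @param labels logical (or 0/1) vector, one label per block; `TRUE` is
#'   flowing. Both classes must be present with at least 2 examples each.
#' @param config a [cnn_config()].
#' @param verbose print per-epoch loss and error rate.
#' @return an object of class `cnn_model` with the trained `weights`, the
#'   `config`, the `input_shape` and a `history` data frame (per-epoch
#'   training `loss` and `error_rate`).
#' @export
train_cnn <- function(blocks, labels, config = cnn_config(),
                      verbose = FALSE) {
  arr <- block_array(blocks)
  labels <- as.logical(labels)
  stopifnot(length(labels) == dim(arr)[4], !anyNA(labels))
  if (min(table(factor(labels, levels = c(FALSE, TRUE)))) < 2)
    stop("training needs at least 2 examples of each class")
  input_shape <- dim(arr)[1:3]
  shapes <- layer_output_shapes(config, input_shape)
  w0 <- init_weights(shapes, config)
  fit <- cnn_train_cpp(arr, as.integer(labels), w0,
                       config$mlp_hidden, config$batch_size,
                       config$max_epochs, config$early_stop_tol,
                       config$early_stop_patience, config$adadelta_rho,
                       config$adadelta_eps, config$seed,
                       config$normalize, verbose)
  structure(list(weights = fit$weights,
                 config = config,
                 input_shape = input_shape,
                 history = data.frame(epoch = seq_along(fit$loss),
                                      loss = fit$loss,
                                      error_rate = fit$error_rate)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<cnn_model> input %s, %d epochs, final training loss",
                     " %.4f (error rate %.3f)\n"),
              paste(x$input_shape, collapse = "x"), nrow(h),
              h$loss[nrow(h)], h$error_rate[nrow(h)]))
  invisible(x)
}

#' Flow probabilities from a trained model
#'
#' Returns the soft-max probability of the flow class for each block. The
#' two soft-max outputs sum to one, so the no-flow probability is the
#' complement.
#'
#' @param object a `cnn_model` or `logistic_baseline`.
#' @param blocks a `block_set` or raw block array.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.cnn_model <- function(object, blocks, ...) {
  arr <- block_array(blocks)
  stopifnot(all(dim(arr)[1:3] == object$input_shape))
  cnn_predict_cpp(arr, object$weights, object$config$mlp_hidden,
                  object$config$normalize)
}

#' Classify one data block
#'
#' Convenience wrapper around [predict.cnn_model()] for a single block.
#'
#' @param model a trained `cnn_model` (or `logistic_baseline`).
#' @param block one data block array `[rows, cols, frames]`.
#' @return the flow probability.
#' @export
predict_pixel <- function(model, block) {
  arr <- array(block, dim = c(dim(block), 1L))
  predict(model, arr)[1]
}

#' K-fold cross-validation of the 3D-CNN
#'
#' Stratified k-fold (default tenfold) cross-validation on a labeled
#' block set, as used for architecture selection. Each fold trains a
#' fresh network on the remaining folds and scores held-out blocks at the
#' pixel level. Not run by any pipeline default — it multiplies the
#' training cost by `k`.
#'
#' @param blocks a `block_set` or raw block array.
#' @param labels logical vector, one per block.
#' @param k number of folds.
#' @param config a [cnn_config()]; its seed drives the fold assignment
#'   and every per-fold training run.
#' @return a data frame with one row per fold (`fold`, `n`, `accuracy`)
#'   and the pooled accuracy as attribute `"accuracy"`.
#' @export
cross_validate_cnn <- function(blocks, labels, k = 10L,
                               config = cnn_config()) {
  arr <- block_array(blocks)
  labels <- as.logical(labels)
  n <- dim(arr)[4]
  stopifnot(length(labels) == n, k >= 2, k <= n)
  set.seed(config$seed)
  folds <- integer(n) # stratified assignment
  for (cls in c(FALSE, TRUE)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  correct <- integer(k)
  counts <- integer(k)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- train_cnn(arr[, , , !hold, drop = FALSE], labels[!hold], config)
    p <- predict(fit, arr[, , , hold, drop = FALSE])
    correct[f] <- sum((p >= config$prob_threshold) == labels[hold])
    counts[f] <- sum(hold)
  }
  out <- data.frame(fold = seq_len(k), n = counts,
                    accuracy = correct / counts)
  attr(out, "accuracy") <- sum(correct) / n
  out
}

#' Vessel-level flow decision from per-pixel probabilities
#'
#' Applies the per-pixel probability threshold (flow when
#' `p >= prob_threshold`), then the cross-section majority rule: the
#' vessel crossing is flowing when strictly more than `majority` of its
#' cross-section pixels are classified flowing. A cross-section of 4
#' pixels with 3 flowing has `flowing_fraction` 0.75 and is flowing; an
#' exactly-half split is not flowing.
#'
#' @param pixel_probabilities non-empty numeric vector in `[0, 1]`.
#' @param prob_threshold per-pixel threshold (default 0.5).
#' @param majority vessel-level majority threshold, strict (default 0.5).
#' @return a list of class `flow_decision`: `probabilities`,
#'   `pixel_flowing`, `flowing_fraction`, `vessel_flowing`.
#' @export
decide_vessel <- function(pixel_probabilities, prob_threshold = 0.5,
                          majority = 0.5) {
  if (length(pixel_probabilities) == 0)
    stop("empty probability list")
  binary <- pixel_probabilities >= prob_threshold
  frac <- mean(binary)
  structure(list(probabilities = pixel_probabilities,
                 pixel_flowing = binary,
                 flowing_fraction = frac,
                 vessel_flowing = frac > majority),
            class = "flow_decision")
}

#' Train the logistic-regression baseline
#'
#' Binary logistic regression in which each (normalized) pixel value of
#' the flattened data block is one input feature — 51,200 coefficients for
#' the standard `16 x 16 x 200` block — with L2 (ridge) regularization.
#' Serves as the comparison baseline for the 3D-CNN and shares its
#' prediction and decision interface.
#'
#' @param blocks a `block_set` or raw block array.
#' @param labels logical vector, one per block.
#' @param lambda ridge penalty (default 1e-2).
#' @param normalize per-block min-max normalization, as for the CNN.
#' @param seed integer seed (the fit itself is deterministic; the seed is
#'   recorded for provenance).
#' @return an object of class `logistic_baseline`.
#' @export
train_logistic_baseline <- function(blocks, labels, lambda = 1e-2,
                                    normalize = TRUE, seed = 1L) {
  arr <- block_array(blocks)
  labels <- as.logical(labels)
  stopifnot(length(labels) == dim(arr)[4], !anyNA(labels))
  if (min(table(factor(labels, levels = c(FALSE, TRUE)))) < 2)
    stop("training needs at least 2 examples of each class")
  x <- flatten_blocks(arr, normalize)
  set.seed(seed)
  fit <- glmnet::glmnet(x, factor(labels, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, normalize = normalize,
                 input_shape = dim(arr)[1:3], seed = seed),
            class = "logistic_baseline")
}

flatten_blocks <- function(arr, normalize) {
  n <- dim(arr)[4]
  m <- matrix(arr, ncol = n)
  if (normalize) {
    mins <- apply(m, 2, min)
    maxs <- apply(m, 2, max)
    span <- maxs - mins
    span[span == 0] <- 1
    m <- (m - rep(mins, each = nrow(m))) / rep(span, each = nrow(m))
    m[, maxs == mins] <- 0
  }
  t(m)
}

#' @export
#' @rdname predict.cnn_model
predict.logistic_baseline <- function(object, blocks, ...) {
  arr <- block_array(blocks)
  stopifnot(all(dim(arr)[1:3] == object$input_shape))
  x <- flatten_blocks(arr, object$normalize)
  as.numeric(predict(object$fit, x, s = object$lambda, type = "response"))
}

#' Coefficients of the logistic baseline
#'
#' @param object a `logistic_baseline`.
#' @param ... unused.
#' @return named list with `intercept` and the flattened-pixel
#'   `coefficients` vector.
#' @export
coef.logistic_baseline <- function(object, ...) {
  cf <- as.numeric(glmnet::coef.glmnet(object$fit, s = object$lambda))
  list(intercept = cf[1], coefficients = cf[-1])
}
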