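#' Confusion matrix of flow classification
#'
#' Counts with flowing as the positive class.
#'
#' @param pred,truth binary vectors (logical or 0/1) of equal length.
#' @return an object of class `confusion_matrix` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1) stop("empty input")
  confusion_matrix(tp = sum(pred & truth), tn = sum(!pred & !truth),
                   fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative integer counts (alternative entry point
#'   for printed confusion tables).
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("true not flowing", "true flowing"),
                              c("pred not flowing", "pred flowing")))
  print(m)
  invisible(x)
}

#' Derived metrics of a confusion matrix
#'
#' The five standard derivations: accuracy `(TP+TN)/(TP+TN+FN+FP)`,
#' positive precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, F1 score
#' `2TP/(2TP+FP+FN)` and negative precision `TN/(TN+FN)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never coerced to 0
#' or 1. Values are kept at full precision; the print method rounds to 2
#' decimals as customary for reported tables.
#'
#' @param cm a [confusion_matrix()].
#' @return a list of class `metric_set` with fields `accuracy`,
#'   `positive_precision`, `sensitivity`, `f1`, `negative_precision`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, structure(list(
    accuracy = safe(tp + tn, tp + tn + fn + fp),
    positive_precision = safe(tp, tp + fp),
    sensitivity = safe(tp, tp + fn),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    negative_precision = safe(tn, tn + fn)),
    class = "metric_set"))
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' Label pipeline crossings from phantom ground truth
#'
#' Attaches the true flow label to each detected crossing by matching its
#' center to the nearest ground-truth grid crossing within
#' `match_radius_px`. Crossings with no true counterpart nearby are
#' labeled non-flowing (they are artifacts, which is exactly what the
#' classifier must learn to reject).
#'
#' @param samples an [find_intersections()] result.
#' @param truth a `phantom_truth` (or its `intersections` data frame).
#' @param match_radius_px center-matching tolerance in px.
#' @return `samples` with logical `label` and `matched` columns.
#' @export
label_crossings <- function(samples, truth, match_radius_px = 3) {
  ti <- if (inherits(truth, "phantom_truth")) truth$intersections else truth
  lab <- logical(nrow(samples))
  matched <- logical(nrow(samples))
  for (k in seq_len(nrow(samples))) {
    d <- sqrt((ti$center_row - samples$center_row[k])^2 +
              (ti$center_col - samples$center_col[k])^2)
    if (length(d) && min(d) <= match_radius_px) {
      matched[k] <- TRUE
      lab[k] <- ti$flowing[which.min(d)]
    }
  }
  samples$label <- lab
  samples$matched <- matched
  samples
}

#' End-to-end detection and error rates against phantom ground truth
#'
#' Compares pipeline flow decisions with a phantom's ground-truth grid
#' crossings. The detection rate is the fraction of truly flowing
#' crossings that the pipeline marks flowing; the error rate is the
#' fraction of crossings marked flowing that are truly non-flowing or
#' artifacts (no true crossing nearby). Crossings are matched by center
#' distance (default 3 px). With no flowing-marked crossings the error
#' rate is undefined and reported as `NA`.
#'
#' @param decisions data frame with columns `center_row`, `center_col`,
#'   `vessel_flowing` (one row per pipeline crossing), as produced by
#'   [run_pipeline()].
#' @param truth a `phantom_truth` (or its `intersections` data frame).
#' @param match_radius_px center-matching tolerance in px.
#' @return a list with `detection_rate`, `error_rate`, `n_true_flowing`,
#'   `n_detected`, `n_marked_flowing`, `n_false_marks`.
#' @export
end_to_end_eval <- function(decisions, truth, match_radius_px = 3) {
  ti <- if (inherits(truth, "phantom_truth")) truth$intersections else truth
  if (is.null(ti) || nrow(ti) == 0) stop("empty ground truth")
  stopifnot(all(c("center_row", "center_col", "vessel_flowing") %in%
                  names(decisions)))
  flowing_truth <- ti[ti$flowing, , drop = FALSE]
  marked <- decisions[decisions$vessel_flowing, , drop = FALSE]
  near <- function(r, c_, tab) {
    if (nrow(tab) == 0) return(FALSE)
    any(sqrt((tab$center_row - r)^2 + (tab$center_col - c_)^2) <=
          match_radius_px)
  }
  detected <- vapply(seq_len(nrow(flowing_truth)), function(k)
    near(flowing_truth$center_row[k], flowing_truth$center_col[k], marked),
    logical(1))
  false_mark <- vapply(seq_len(nrow(marked)), function(k)
    !near(marked$center_row[k], marked$center_col[k], flowing_truth),
    logical(1))
  list(detection_rate = if (nrow(flowing_truth)) mean(detected) else NA_real_,
       error_rate = if (nrow(marked)) mean(false_mark) else NA_real_,
       n_true_flowing = nrow(flowing_truth),
       n_detected = sum(detected),
       n_marked_flowing = nrow(marked),
       n_false_marks = sum(false_mark))
}
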