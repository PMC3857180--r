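# Detection evaluation: greedy matching of detections to ground truth and
# precision/recall.

#' Match detections to ground-truth points
#'
#' Greedy one-to-one matching in descending detection-score order (ties
#' broken by smaller y, then smaller x): each detection matches the
#' nearest still-unmatched truth point within `tolerance_px`.  Unmatched
#' detections count as false positives, unmatched truths as false
#' negatives.
#'
#' @param detections data frame with `x`, `y` and optionally `score`
#'   (missing scores are treated as equal).
#' @param truth data frame or matrix with `x`, `y` columns.
#' @param tolerance_px matching radius in pixels (> 0).
#' @return list with integer `tp`, `fp`, `fn` and a logical
#'   `matched_truth` vector.
#' @export
match_detections <- function(detections, truth, tolerance_px) {
  stopifnot(tolerance_px > 0)
  truth <- as.data.frame(truth)
  n_t <- nrow(truth)
  n_d <- nrow(detections)
  if (n_d == 0)
    return(list(tp = 0L, fp = 0L, fn = n_t,
                matched_truth = rep(FALSE, n_t)))
  sc <- if ("score" %in% names(detections)) detections$score else
    rep(0, n_d)
  ord <- order(-sc, detections$y, detections$x)
  matched <- rep(FALSE, n_t)
  tp <- 0L
  for (i in ord) {
    if (n_t == 0) break
    d2 <- (truth$x - detections$x[i])^2 + (truth$y - detections$y[i])^2
    d2[matched] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tolerance_px^2) {
      matched[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = n_d - tp, fn = n_t - tp, matched_truth = matched)
}

#' Precision and recall from match counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`; ratios with a
#' zero denominator are reported as `NA` rather than 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @param match_tolerance_px the tolerance used for matching (recorded).
#' @return list of class `detection_metrics` with `tp`, `fp`, `fn`,
#'   `precision`, `recall` (proportions in `[0, 1]` or `NA`), and
#'   `match_tolerance_px`.
#' @export
precision_recall <- function(tp, fp, fn, match_tolerance_px = NA_real_) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision,
                 recall = recall,
                 match_tolerance_px = match_tolerance_px),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.1f%%", 100 * v)
  cat(sprintf("Detection metrics: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %s, recall %s\n", fmt(x$precision),
              fmt(x$recall)))
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' Convenience wrapper: [match_detections()] followed by
#' [precision_recall()].
#'
#' @inheritParams match_detections
#' @return a `detection_metrics` object.
#' @export
evaluate_detections <- function(detections, truth, tolerance_px) {
  m <- match_detections(detections, truth, tolerance_px)
  precision_recall(m$tp, m$fp, m$fn, tolerance_px)
}
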