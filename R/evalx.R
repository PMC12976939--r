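# Detection evaluation: confidence-ordered greedy matching at an IOU
# threshold, precision/recall/F1, confidence-precision curves, and
# interobserver agreement between annotators.

#' Match detections to ground-truth boxes
#'
#' Detections are processed in descending confidence; each claims the
#' still-unmatched truth box with the highest IOU strictly greater than
#' `iou_thresh` (ties to the lowest truth index). Detections that claim
#' nothing are false positives; truths never claimed are false negatives.
#' This is the standard one-to-one assignment used in detection
#' benchmarks.
#'
#' @param dets detections data frame (`x0`, `y0`, `x1`, `y1`,
#'   `confidence`).
#' @param truths ground-truth box data frame.
#' @param iou_thresh matching threshold in `(0, 1]`; overlap must strictly
#'   exceed it (set `strict = FALSE` for at-or-above).
#' @param strict if `TRUE` (default) require IOU > threshold, else >=.
#' @return A `match_result`: `tp`, `fp`, `fn` counts and `matched_pairs`
#'   (detection index, truth index, IOU).
#' @export
match_detections <- function(dets, truths, iou_thresh = 0.5, strict = TRUE) {
  validate_boxes(truths)
  stopifnot(is.data.frame(dets))
  if (!is.numeric(iou_thresh) || iou_thresh <= 0 || iou_thresh > 1) {
    stop_invalid("iou_thresh must lie in (0, 1]")
  }
  nd <- nrow(dets)
  nt <- nrow(truths)
  pairs <- data.frame(det = integer(0), truth = integer(0), iou = numeric(0))
  if (nd > 0L && nt > 0L) {
    validate_boxes(dets)
    m <- iou_matrix(dets, truths)
    used <- logical(nt)
    ord <- order(dets$confidence, decreasing = TRUE)
    for (i in ord) {
      cand <- m[i, ]
      cand[used] <- -1
      j <- which.max(cand)
      hit <- if (strict) cand[j] > iou_thresh else cand[j] >= iou_thresh
      if (hit) {
        used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, truth = j, iou = m[i, j]))
      }
    }
  }
  tp <- nrow(pairs)
  structure(
    list(
      tp = tp, fp = nd - tp, fn = nt - tp,
      matched_pairs = pairs, iou_thresh = iou_thresh
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d | FP %d | FN %d (IOU > %.2f)\n",
    x$tp, x$fp, x$fn, x$iou_thresh
  ))
  invisible(x)
}

#' Precision, recall, and F1 from raw counts
#'
#' Precision is the positive predictive value `tp / (tp + fp)`, recall the
#' sensitivity `tp / (tp + fn)`, and F1 their harmonic mean. Degenerate
#' denominators are flagged undefined (`NA` plus a `defined` flag) rather
#' than silently zeroed, so cohort aggregation cannot absorb empty cells.
#'
#' @param tp,fp,fn non-negative counts (or pass a `match_result` as `tp`).
#' @return An `eval_metrics` object with `precision`, `recall`, `f1`, and
#'   logical `defined` flags.
#' @examples
#' detection_metrics(101, 22, 27)
#' @export
detection_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    m <- tp
    tp <- m$tp
    fp <- m$fp
    fn <- m$fn
  }
  stopifnot(is_count(tp), is_count(fp), is_count(fn))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(
    list(
      tp = tp, fp = fp, fn = fn,
      precision = precision, recall = recall, f1 = f1,
      defined = c(
        precision = !is.na(precision), recall = !is.na(recall),
        f1 = !is.na(f1)
      )
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.*f", digits, round_half_up(v, digits))
  cat(sprintf(
    "<eval_metrics> precision %s | recall %s | F1 %s (TP %d, FP %d, FN %d)\n",
    fmt(x$precision), fmt(x$recall), fmt(x$f1), x$tp, x$fp, x$fn
  ))
  invisible(x)
}

# display rounding used in reports: half-up, as fractions or whole percent
round_metric <- function(x, digits = 2) round_half_up(x, digits)
percent_metric <- function(x) round_half_up(100 * x)

#' Confidence-precision curve
#'
#' For each threshold: filter detections by confidence, match against the
#' truths, and record the precision. The curve is the evidence on which an
#' operating confidence threshold (here 0.5) is chosen.
#'
#' @param dets detections data frame.
#' @param truths ground-truth boxes.
#' @param thresholds confidence grid in `[0, 1]`.
#' @param iou_thresh matching threshold.
#' @return Data frame with `threshold`, `precision`, `recall`, `n_dets`.
#' @export
confidence_precision_curve <- function(dets, truths,
                                       thresholds = seq(0, 1, by = 0.05),
                                       iou_thresh = 0.5) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  rows <- lapply(thresholds, function(t) {
    kept <- filter_by_confidence(dets, t)
    m <- detection_metrics(match_detections(kept, truths, iou_thresh))
    data.frame(
      threshold = t, precision = m$precision, recall = m$recall,
      n_dets = nrow(kept)
    )
  })
  do.call(rbind, rows)
}

#' Interobserver agreement between two annotation sets
#'
#' Treats `b` as ground truth and `a` as predictions at uniform confidence;
#' with all confidences equal, pairs are claimed in descending IOU. Returns
#' precision/recall/F1 of annotator `a` against annotator `b`.
#'
#' @param a,b [annotation_set()] objects on the same image dimensions.
#' @param iou_thresh matching threshold (overlap must strictly exceed it).
#' @return An `eval_metrics` object.
#' @export
interobserver_metrics <- function(a, b, iou_thresh = 0.5) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  if (a$image_w != b$image_w || a$image_h != b$image_h) {
    stop_invalid("annotation sets refer to different image dimensions")
  }
  pa <- from_normalized(a$boxes, a$image_w, a$image_h)
  pb <- from_normalized(b$boxes, b$image_w, b$image_h)
  na <- nrow(pa)
  nb <- nrow(pb)
  tp <- 0L
  if (na > 0L && nb > 0L) {
    m <- iou_matrix(pa, pb)
    used_a <- logical(na)
    used_b <- logical(nb)
    for (k in order(m, decreasing = TRUE)) {
      if (m[k] <= iou_thresh) break
      i <- (k - 1L) %% na + 1L
      j <- (k - 1L) %/% na + 1L
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      tp <- tp + 1L
    }
  }
  detection_metrics(tp, na - tp, nb - tp)
}

#' Evaluate detections against truths per image and pooled
#'
#' @param det_sets named list of detections data frames, keyed by image id.
#' @param truth_sets named list of truth box data frames with the same
#'   names.
#' @param iou_thresh matching threshold.
#' @return List with `per_image` (data frame of counts and metrics) and
#'   `pooled` (an `eval_metrics` over summed counts).
#' @export
evaluate_detections <- function(det_sets, truth_sets, iou_thresh = 0.5) {
  ids <- names(truth_sets)
  missing <- setdiff(ids, names(det_sets))
  extra <- setdiff(names(det_sets), ids)
  if (length(missing) || length(extra)) {
    stop_invalid(
      "image id mismatch; missing from detections: %s; unknown: %s",
      paste(missing, collapse = ","), paste(extra, collapse = ",")
    )
  }
  rows <- lapply(ids, function(id) {
    m <- match_detections(det_sets[[id]], truth_sets[[id]], iou_thresh)
    e <- detection_metrics(m)
    data.frame(
      image_id = id, tp = m$tp, fp = m$fp, fn = m$fn,
      precision = e$precision, recall = e$recall, f1 = e$f1
    )
  })
  per_image <- do.call(rbind, rows)
  pooled <- detection_metrics(sum(per_image$tp), sum(per_image$fp), sum(per_image$fn))
  list(per_image = per_image, pooled = pooled)
}
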