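# Independent oracles used across the suite.

# IOU by rasterizing both boxes on the integer pixel grid and counting
# covered cells; valid for integer-coordinate boxes
raster_iou <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  xs <- seq(min(a[1], b[1]), max(a[3], b[3]) - 1)
  ys <- seq(min(a[2], b[2]), max(a[4], b[4]) - 1)
  in_box <- function(bx) {
    outer(ys >= bx[2] & ys < bx[4], xs >= bx[1] & xs < bx[3], `&`)
  }
  ma <- in_box(a)
  mb <- in_box(b)
  inter <- sum(ma & mb)
  union <- sum(ma | mb)
  inter / union
}

# maximum-cardinality matching of detections to truths over pairs with
# IOU strictly above thresh, by exhaustive branch and bound
exhaustive_max_tp <- function(iou_mat, thresh = 0.5) {
  nd <- nrow(iou_mat)
  nt <- ncol(iou_mat)
  if (nd == 0L || nt == 0L) {
    return(0L)
  }
  best <- 0L
  rec <- function(i, used, cur) {
    if (cur + (nd - i + 1L) <= best) {
      return()
    }
    if (i > nd) {
      best <<- max(best, cur)
      return()
    }
    rec(i + 1L, used, cur) # detection i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou_mat[i, j] > thresh) {
        used[j] <- TRUE
        rec(i + 1L, used, cur + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0L)
  best
}

# random integer box within a bounded canvas
random_int_box <- function(max_xy = 60, max_side = 30) {
  x0 <- sample.int(max_xy, 1) - 1L
  y0 <- sample.int(max_xy, 1) - 1L
  c(x0, y0, x0 + sample.int(max_side, 1), y0 + sample.int(max_side, 1))
}

# display rounding oracle: half-up (base round() is banker's)
rhu <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

percent_metric_for_test <- function(m) {
  unname(rhu(100 * c(m$precision, m$recall, m$f1)))
}

empty_detections_for_test <- function() {
  data.frame(
    x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
    confidence = numeric(0)
  )
}

as_box_df <- function(v) {
  data.frame(x0 = v[1], y0 = v[2], x1 = v[3], y1 = v[4])
}

# detections data frame from a matrix of boxes plus confidences
dets_df <- function(boxes, conf) {
  data.frame(
    x0 = boxes[, 1], y0 = boxes[, 2], x1 = boxes[, 3], y1 = boxes[, 4],
    confidence = conf
  )
}

# annotation set from a pixel-box data frame
annot_from_pixels <- function(id, w, h, px) {
  annotation_set(id, w, h, to_normalized(px, w, h, 0L))
}
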