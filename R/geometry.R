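#' Axis-aligned pixel bounding box
#'
#' Boxes use half-open pixel intervals `[x0, x1) x [y0, y1)` with a 0-based
#' origin at the image's top-left, so integer boxes have integer areas and
#' abutting boxes tile without gaps or double counting.
#'
#' @param x0,y0 left/top edge (inclusive), pixels.
#' @param x1,y1 right/bottom edge (exclusive), pixels; must exceed `x0`/`y0`.
#' @return A one-row data frame with columns `x0`, `y0`, `x1`, `y1`.
#' @examples
#' box(0, 0, 40, 40)
#' @export
box <- function(x0, y0, x1, y1) {
  b <- data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b), all(c("x0", "y0", "x1", "y1") %in% names(b)))
  if (nrow(b) == 0L) {
    return(invisible(b))
  }
  if (any(!is.finite(b$x0) | !is.finite(b$y0) | !is.finite(b$x1) | !is.finite(b$y1))) {
    stop_invalid("box coordinates must be finite")
  }
  if (any(b$x1 <= b$x0) || any(b$y1 <= b$y0)) {
    stop_invalid("degenerate box: x1 must exceed x0 and y1 must exceed y0")
  }
  invisible(b)
}

as_box_row <- function(b) {
  if (is.numeric(b) && length(b) == 4L) {
    b <- data.frame(x0 = b[[1]], y0 = b[[2]], x1 = b[[3]], y1 = b[[4]])
  }
  validate_boxes(b)
  if (nrow(b) != 1L) stop_invalid("expected a single box")
  b
}

#' Intersection over union of two boxes
#'
#' Computed on continuous box areas (the standard detection-evaluation
#' definition), not on a rasterized grid.
#'
#' @param a,b boxes: either one-row data frames from [box()] or length-4
#'   numeric vectors `c(x0, y0, x1, y1)`.
#' @return Overlap fraction in `[0, 1]`; 0 when the boxes are disjoint.
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  a <- as_box_row(a)
  b <- as_box_row(b)
  ix <- min(a$x1, b$x1) - max(a$x0, b$x0)
  iy <- min(a$y1, b$y1) - max(a$y0, b$y0)
  if (ix <= 0 || iy <= 0) {
    return(0)
  }
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

#' Pairwise IOU matrix between two box sets
#'
#' @param a,b data frames of boxes (columns `x0`, `y0`, `x1`, `y1`).
#' @return A `nrow(a)` x `nrow(b)` matrix of IOU values.
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  na <- nrow(a)
  nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    return(matrix(numeric(0), na, nb))
  }
  ix <- outer(a$x1, b$x1, pmin) - outer(a$x0, b$x0, pmax)
  iy <- outer(a$y1, b$y1, pmin) - outer(a$y0, b$y0, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  area_a <- (a$x1 - a$x0) * (a$y1 - a$y0)
  area_b <- (b$x1 - b$x0) * (b$y1 - b$y0)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Normalized (fractional) bounding box
#'
#' The label-file representation: class index plus centre, width, and height
#' expressed as fractions of the image dimensions, all in `[0, 1]`, with the
#' box lying fully inside the unit square.
#'
#' @param cls integer class index (0 = neutrophil).
#' @param xc,yc box centre as fractions of image width/height.
#' @param w,h box width/height as fractions of image width/height.
#' @return A one-row data frame with columns `cls`, `xc`, `yc`, `w`, `h`.
#' @export
normalized_box <- function(cls, xc, yc, w, h) {
  nb <- data.frame(cls = as.integer(cls), xc = xc, yc = yc, w = w, h = h)
  validate_normalized(nb)
  nb
}

validate_normalized <- function(nb, where = NULL) {
  stopifnot(is.data.frame(nb), all(c("cls", "xc", "yc", "w", "h") %in% names(nb)))
  if (nrow(nb) == 0L) {
    return(invisible(nb))
  }
  ctx <- if (is.null(where)) "" else paste0(" in ", where)
  vals <- c(nb$xc, nb$yc, nb$w, nb$h)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop_invalid("normalized coordinates must lie in [0, 1]%s", ctx)
  }
  if (any(nb$w <= 0) || any(nb$h <= 0)) {
    stop_invalid("normalized box width/height must be positive%s", ctx)
  }
  eps <- 1e-9
  if (any(nb$xc - nb$w / 2 < -eps) || any(nb$xc + nb$w / 2 > 1 + eps) ||
    any(nb$yc - nb$h / 2 < -eps) || any(nb$yc + nb$h / 2 > 1 + eps)) {
    stop_invalid("normalized box extends outside the unit square%s", ctx)
  }
  invisible(nb)
}

#' Convert pixel boxes to normalized form
#'
#' @param b pixel boxes (data frame or length-4 vector); must lie within the
#'   image bounds.
#' @param image_w,image_h image dimensions in pixels.
#' @param cls class index to attach (recycled).
#' @return Normalized boxes (data frame with `cls`, `xc`, `yc`, `w`, `h`).
#' @export
to_normalized <- function(b, image_w, image_h, cls = 0L) {
  if (is.numeric(b) && length(b) == 4L) b <- as_box_row(b)
  validate_boxes(b)
  if (nrow(b) > 0 &&
    (any(b$x0 < 0) || any(b$y0 < 0) || any(b$x1 > image_w) || any(b$y1 > image_h))) {
    stop_invalid("box exceeds image bounds (%d x %d)", image_w, image_h)
  }
  nb <- data.frame(
    cls = as.integer(rep_len(cls, nrow(b))),
    xc = (b$x0 + b$x1) / 2 / image_w,
    yc = (b$y0 + b$y1) / 2 / image_h,
    w = (b$x1 - b$x0) / image_w,
    h = (b$y1 - b$y0) / image_h
  )
  validate_normalized(nb)
  nb
}

#' Convert normalized boxes to pixel form
#'
#' Left/top edges round half-up; the right/bottom edge is derived as
#' `x0 + round(w * image_w)` so box width is stable under round trips.
#'
#' @param nb normalized boxes (data frame with `xc`, `yc`, `w`, `h`).
#' @param image_w,image_h image dimensions in pixels.
#' @return Pixel boxes (data frame with `x0`, `y0`, `x1`, `y1`).
#' @examples
#' from_normalized(normalized_box(0, 0.2, 0.4, 0.2, 0.4), 100, 100)
#' @export
from_normalized <- function(nb, image_w, image_h) {
  validate_normalized(nb)
  if (nrow(nb) == 0L) {
    return(box(0, 0, 1, 1)[0, ])
  }
  x0 <- round_half_up(nb$xc * image_w - nb$w * image_w / 2)
  y0 <- round_half_up(nb$yc * image_h - nb$h * image_h / 2)
  b <- data.frame(
    x0 = x0, y0 = y0,
    x1 = x0 + round_half_up(nb$w * image_w),
    y1 = y0 + round_half_up(nb$h * image_h)
  )
  validate_boxes(b)
  b
}
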