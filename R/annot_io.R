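#' Annotation set for one image
#'
#' Couples an image identifier and its pixel dimensions with a table of
#' normalized bounding boxes, the unit in which label files are read and
#' written.
#'
#' @param image_id identifier (typically the image file stem).
#' @param image_w,image_h image dimensions in pixels.
#' @param boxes data frame of normalized boxes (`cls`, `xc`, `yc`, `w`, `h`);
#'   defaults to an empty set.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, image_w, image_h,
                           boxes = normalized_box(0L, 0.5, 0.5, 1, 1)[0, ]) {
  stopifnot(length(image_id) == 1L, is_count(image_w), is_count(image_h))
  validate_normalized(boxes, where = image_id)
  structure(
    list(
      image_id = as.character(image_id),
      image_w = as.integer(image_w), image_h = as.integer(image_h),
      boxes = boxes
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %s (%d x %d px), %d box(es)\n",
    x$image_id, x$image_w, x$image_h, nrow(x$boxes)
  ))
  invisible(x)
}

#' Read a normalized label file
#'
#' Parses the one-box-per-line text format `"cls xc yc w h"` with all
#' coordinates normalized to `[0, 1]`. An empty file yields an empty set.
#'
#' @param path label file path.
#' @param image_w,image_h dimensions of the image the labels belong to.
#' @param image_id identifier; defaults to the file stem.
#' @return An [annotation_set()].
#' @export
read_labels <- function(path, image_w, image_h,
                        image_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_invalid("label file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(annotation_set(image_id, image_w, image_h))
  }
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(fields) != 5L) {
      stop_invalid(
        "%s line %d: expected 5 fields, found %d",
        path, i, length(fields)
      )
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_invalid("%s line %d: non-numeric field", path, i)
    }
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1)) {
      stop_invalid("%s line %d: coordinate outside [0, 1]", path, i)
    }
    data.frame(cls = as.integer(vals[1]), xc = vals[2], yc = vals[3], w = vals[4], h = vals[5])
  })
  boxes <- do.call(rbind, rows)
  validate_normalized(boxes, where = path)
  annotation_set(image_id, image_w, image_h, boxes)
}

#' Write a normalized label file
#'
#' Inverse of [read_labels()]: one line per box, space-separated, class
#' first, coordinates at 6 decimal places. An empty set produces a
#' zero-byte file.
#'
#' @param a an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  b <- a$boxes
  lines <- if (nrow(b) == 0L) {
    character(0)
  } else {
    sprintf("%d %.6f %.6f %.6f %.6f", b$cls, b$xc, b$yc, b$w, b$h)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Rescale an image and its annotations together
#'
#' Resizes the raster by `factor` (bilinear, via EBImage) and carries the
#' annotation set across. Normalized coordinates are unchanged in value
#' because normalization absorbs the scaling; only the recorded pixel
#' dimensions change. Typical use is shrinking source images until the
#' target object occupies roughly 40 x 40 pixels, the scale at which
#' neutrophils appear in scanned H&E sections.
#'
#' @param image raster array `[y, x, channel]` with values in `[0, 1]`.
#' @param labels the matching [annotation_set()].
#' @param factor positive scale factor; output dimensions are
#'   `round(input * factor)` (half-up).
#' @return List with elements `image` and `labels`.
#' @export
rescale_annotated <- function(image, labels, factor) {
  stopifnot(is.array(image), length(dim(image)) == 3L, inherits(labels, "annotation_set"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop_invalid("factor must be a positive number")
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  new_h <- as.integer(round_half_up(h * factor))
  new_w <- as.integer(round_half_up(w * factor))
  if (new_h < 2L || new_w < 2L) {
    stop_invalid("rescaled image would be degenerate (%d x %d px)", new_w, new_h)
  }
  if (new_h == h && new_w == w) {
    out <- image
  } else {
    eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    out <- aperm(as.array(EBImage::resize(eb, w = new_w, h = new_h)), c(2, 1, 3))
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  list(
    image = out,
    labels = annotation_set(labels$image_id, new_w, new_h, labels$boxes)
  )
}

#' Merge two annotators' box sets into a proposed consensus
#'
#' Pairs boxes across the two sets greedily in descending IOU; pairs at or
#' above `iou_thresh` become agreed boxes (the coordinate-wise mean of the
#' matched pixel boxes), everything unmatched is routed to the respective
#' disputed list for human review. The function proposes; adjudication of
#' disputes stays with the pathologist.
#'
#' @param a,b [annotation_set()] objects for the same image (dimensions must
#'   match).
#' @param iou_thresh minimum IOU for automatic agreement (default 0.5).
#' @return An object of class `consensus_report` with pixel-box data frames
#'   `agreed`, `disputed_a_only`, `disputed_b_only`.
#' @export
consensus_merge <- function(a, b, iou_thresh = 0.5) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  if (a$image_w != b$image_w || a$image_h != b$image_h) {
    stop_invalid(
      "image dimensions differ: %d x %d vs %d x %d",
      a$image_w, a$image_h, b$image_w, b$image_h
    )
  }
  pa <- from_normalized(a$boxes, a$image_w, a$image_h)
  pb <- from_normalized(b$boxes, b$image_w, b$image_h)
  na <- nrow(pa)
  nb <- nrow(pb)
  used_a <- logical(na)
  used_b <- logical(nb)
  agreed <- list()
  if (na > 0L && nb > 0L) {
    m <- iou_matrix(pa, pb)
    ord <- order(m, decreasing = TRUE)
    for (k in ord) {
      if (m[k] < iou_thresh) break
      i <- (k - 1L) %% na + 1L
      j <- (k - 1L) %/% na + 1L
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      agreed[[length(agreed) + 1L]] <- (pa[i, ] + pb[j, ]) / 2
    }
  }
  structure(
    list(
      agreed = if (length(agreed)) do.call(rbind, agreed) else pa[0, ],
      disputed_a_only = pa[!used_a, , drop = FALSE],
      disputed_b_only = pb[!used_b, , drop = FALSE],
      iou_thresh = iou_thresh
    ),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "<consensus_report> agreed %d | disputed A-only %d | disputed B-only %d (IOU >= %.2f)\n",
    nrow(x$agreed), nrow(x$disputed_a_only), nrow(x$disputed_b_only), x$iou_thresh
  ))
  invisible(x)
}

#' Apply an exclusion list to an annotation set
#'
#' Removes listed boxes (by row index) after consensus, mirroring the
#' workflow step in which uncertain ground-truth identifications are struck
#' out by an expert reviewer rather than by the software.
#'
#' @param a an [annotation_set()].
#' @param exclude integer row indices of boxes to drop.
#' @return The reduced [annotation_set()].
#' @export
exclude_boxes <- function(a, exclude) {
  stopifnot(inherits(a, "annotation_set"))
  if (length(exclude) == 0L) {
    return(a)
  }
  exclude <- as.integer(exclude)
  if (any(exclude < 1L) || any(exclude > nrow(a$boxes))) {
    stop_invalid("exclusion index out of range")
  }
  annotation_set(a$image_id, a$image_w, a$image_h, a$boxes[-exclude, , drop = FALSE])
}
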