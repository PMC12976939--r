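# Whole-slide geometry: physical calibration to high-powered-field tiles,
# overlapping sliding-window plans for sliced detection, and merging of
# per-window detections back into slide coordinates.

#' Scanner calibration
#'
#' @param px_per_mm scanner resolution in pixels per millimetre (reference
#'   value 4050 for the calibrated slide scanner).
#' @param hpf_area area of one high-powered field in mm^2 (reference 0.2,
#'   chosen to replicate the ~0.196 mm^2 field of a conventional light
#'   microscope at high power).
#' @return A `calibration` object.
#' @export
calibration <- function(px_per_mm = 4050, hpf_area = 0.2) {
  stopifnot(is.numeric(px_per_mm), px_per_mm > 0, is.numeric(hpf_area), hpf_area > 0)
  structure(list(px_per_mm = px_per_mm, hpf_area = hpf_area), class = "calibration")
}

#' Side of one high-powered-field tile in pixels
#'
#' HPF tiles are square with side `sqrt(hpf_area) * px_per_mm`, rounded
#' half-up; the square best approximates the circular microscope field of
#' the same area. At the reference calibration this is 1811 px.
#'
#' @param c a [calibration()].
#' @return Tile side in whole pixels.
#' @examples
#' hpf_side(calibration(4050, 0.2)) # 1811
#' @export
hpf_side <- function(c = calibration()) {
  stopifnot(inherits(c, "calibration"))
  as.integer(round_half_up(sqrt(c$hpf_area) * c$px_per_mm))
}

#' Tile a slide into high-powered-field equivalents
#'
#' Raster-order grid with stride equal to the tile side; tiles at the right
#' and bottom edges are truncated at the slide bounds and kept, so the tile
#' areas sum exactly to the slide area.
#'
#' @param slide_w,slide_h slide dimensions in pixels.
#' @param c a [calibration()] (or pass `side` directly).
#' @param side tile side override in pixels.
#' @return An `hpf_grid`: list with `tiles` (box data frame, raster order),
#'   `tile_side`, `slide_w`, `slide_h`, `nx`, `ny`.
#' @export
make_hpf_grid <- function(slide_w, slide_h, c = calibration(), side = hpf_side(c)) {
  stopifnot(is_count(slide_w), slide_w >= 1, is_count(slide_h), slide_h >= 1, is_count(side))
  nx <- ceiling(slide_w / side)
  ny <- ceiling(slide_h / side)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  tiles <- data.frame(
    x0 = ix * side, y0 = iy * side,
    x1 = pmin((ix + 1L) * side, slide_w),
    y1 = pmin((iy + 1L) * side, slide_h)
  )
  structure(
    list(
      tiles = tiles, tile_side = as.integer(side),
      slide_w = as.integer(slide_w), slide_h = as.integer(slide_h),
      nx = as.integer(nx), ny = as.integer(ny)
    ),
    class = "hpf_grid"
  )
}

#' @export
print.hpf_grid <- function(x, ...) {
  cat(sprintf(
    "<hpf_grid> %d x %d tiles of side %d px over a %d x %d px slide\n",
    x$nx, x$ny, x$tile_side, x$slide_w, x$slide_h
  ))
  invisible(x)
}

# per-axis window offsets: stride floor(window * (1 - overlap)), final
# offset clamped flush to the far edge so coverage is complete
axis_offsets <- function(dim, window, overlap) {
  if (dim <= window) {
    return(0L)
  }
  stride <- floor(window * (1 - overlap))
  stride <- max(1L, stride)
  offs <- seq.int(0L, dim - window, by = stride)
  if (offs[length(offs)] != dim - window) offs <- c(offs, dim - window)
  as.integer(offs)
}

#' Plan overlapping detection windows over a slide
#'
#' Sliding windows of side `window` with fractional `overlap` between
#' neighbours (reference: a 512 px window with 30% overlap, stride 358).
#' Every slide pixel falls in at least one window; edge windows are clamped
#' flush to the slide bounds, and windows are full-size whenever the slide
#' is at least one window wide.
#'
#' @param slide_w,slide_h slide dimensions in pixels.
#' @param window window side in pixels.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return A `window_plan`: list with `windows` (box data frame), `window`,
#'   `overlap`, `stride`, `slide_w`, `slide_h`.
#' @export
plan_windows <- function(slide_w, slide_h, window = 512L, overlap = 0.3) {
  stopifnot(is_count(slide_w), is_count(slide_h), is_count(window), window >= 1)
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    stop_invalid("overlap must lie in [0, 1)")
  }
  wx <- min(window, slide_w)
  wy <- min(window, slide_h)
  ox <- axis_offsets(slide_w, wx, overlap)
  oy <- axis_offsets(slide_h, wy, overlap)
  grid <- expand.grid(x0 = ox, y0 = oy)
  windows <- data.frame(
    x0 = grid$x0, y0 = grid$y0,
    x1 = grid$x0 + wx, y1 = grid$y0 + wy
  )
  structure(
    list(
      windows = windows, window = as.integer(window), overlap = overlap,
      stride = as.integer(max(1L, floor(window * (1 - overlap)))),
      slide_w = as.integer(slide_w), slide_h = as.integer(slide_h)
    ),
    class = "window_plan"
  )
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf(
    "<window_plan> %d windows of %d px, overlap %.0f%% (stride %d) over %d x %d px\n",
    nrow(x$windows), x$window, 100 * x$overlap, x$stride, x$slide_w, x$slide_h
  ))
  invisible(x)
}

#' Merge per-window detections into slide coordinates
#'
#' Translates each window's detections by its offset, then removes
#' duplicates arising from window overlap by greedy non-maximum
#' suppression: processing in descending confidence, a detection is dropped
#' if it overlaps an already-kept detection with IOU at or above
#' `dedup_iou`.
#'
#' @param per_window list of detections data frames in window-local
#'   coordinates, one per row of `plan$windows`.
#' @param plan the [plan_windows()] result the detections came from.
#' @param dedup_iou IOU at or above which two detections are duplicates.
#' @return Merged detections in slide coordinates, descending confidence.
#' @export
merge_window_detections <- function(per_window, plan, dedup_iou = 0.5) {
  stopifnot(inherits(plan, "window_plan"), is.list(per_window))
  if (length(per_window) != nrow(plan$windows)) {
    stop_invalid(
      "per_window has %d entries but the plan has %d windows",
      length(per_window), nrow(plan$windows)
    )
  }
  translated <- lapply(seq_along(per_window), function(i) {
    d <- per_window[[i]]
    if (is.null(d) || nrow(d) == 0L) {
      return(NULL)
    }
    w <- plan$windows[i, ]
    ww <- w$x1 - w$x0
    wh <- w$y1 - w$y0
    if (any(d$x0 < 0) || any(d$y0 < 0) || any(d$x1 > ww) || any(d$y1 > wh)) {
      stop_invalid("window %d: detection outside window bounds", i)
    }
    data.frame(
      x0 = d$x0 + w$x0, y0 = d$y0 + w$y0,
      x1 = d$x1 + w$x0, y1 = d$y1 + w$y0,
      confidence = d$confidence
    )
  })
  all <- do.call(rbind, translated[!vapply(translated, is.null, logical(1))])
  if (is.null(all) || nrow(all) == 0L) {
    return(empty_detections())
  }
  dedup_detections(all, dedup_iou)
}

# greedy confidence-ordered NMS on slide-coordinate detections
dedup_detections <- function(dets, dedup_iou = 0.5) {
  ord <- order(dets$confidence, decreasing = TRUE)
  d <- dets[ord, , drop = FALSE]
  keep <- nms_keep_cpp(as.matrix(d[, c("x0", "y0", "x1", "y1", "confidence")]), dedup_iou)
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a detector over a slide through a window plan
#'
#' Plans windows, runs the detector on each, and merges the per-window
#' detections into slide coordinates. With the built-in reference detector
#' a fast path reads each window directly from the slide array and
#' suppresses candidates hugging interior window cuts (each such object is
#' seen whole by an overlapping neighbour window, and duplicate sightings
#' are resolved by the merge step).
#'
#' @param slide raster array `[y, x, 3]`.
#' @param window,overlap window geometry (see [plan_windows()]).
#' @param scale expected object side in pixels.
#' @param detector detector function `tile -> detections`; default is the
#'   reference detector fast path.
#' @param dedup_iou duplicate-suppression IOU for the merge step.
#' @return Detections in slide coordinates, descending confidence.
#' @export
detect_slide <- function(slide, window = 512L, overlap = 0.3, scale = 40,
                         detector = NULL, dedup_iou = 0.5) {
  H <- dim(slide)[1]
  W <- dim(slide)[2]
  plan <- plan_windows(W, H, window = window, overlap = overlap)
  if (is.null(detector)) {
    dets <- lapply(seq_len(nrow(plan$windows)), function(i) {
      w <- plan$windows[i, ]
      open <- c(w$x0 > 0, w$y0 > 0, w$x1 < W, w$y1 < H)
      detect_region(slide, c(w$x0, w$y0, w$x1, w$y1), scale = scale, open_edges = open)
    })
    all <- do.call(rbind, dets)
    if (is.null(all) || nrow(all) == 0L) {
      return(empty_detections())
    }
    dedup_detections(all, dedup_iou)
  } else {
    per_window <- lapply(seq_len(nrow(plan$windows)), function(i) {
      w <- plan$windows[i, ]
      crop <- slide[(w$y0 + 1):w$y1, (w$x0 + 1):w$x1, , drop = FALSE]
      detector(crop)
    })
    merge_window_detections(per_window, plan, dedup_iou = dedup_iou)
  }
}

#' Count detections per high-powered-field tile
#'
#' Assigns each detection to the grid tile containing its box centre.
#' Centres falling exactly on an interior tile boundary go to the
#' lower-index tile, so every detection is counted exactly once.
#'
#' @param dets detections in slide coordinates.
#' @param grid an [make_hpf_grid()] result.
#' @return Integer vector of counts, one per grid tile (raster order).
#' @export
count_by_hpf <- function(dets, grid) {
  stopifnot(inherits(grid, "hpf_grid"))
  n_tiles <- nrow(grid$tiles)
  if (nrow(dets) == 0L) {
    return(integer(n_tiles))
  }
  cx <- (dets$x0 + dets$x1) / 2
  cy <- (dets$y0 + dets$y1) / 2
  side <- grid$tile_side
  ix <- floor(cx / side)
  on_edge_x <- cx %% side == 0 & cx > 0
  ix[on_edge_x] <- ix[on_edge_x] - 1
  iy <- floor(cy / side)
  on_edge_y <- cy %% side == 0 & cy > 0
  iy[on_edge_y] <- iy[on_edge_y] - 1
  ix <- pmin(pmax(ix, 0), grid$nx - 1)
  iy <- pmin(pmax(iy, 0), grid$ny - 1)
  idx <- iy * grid$nx + ix + 1
  counts <- integer(n_tiles)
  tab <- table(idx)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Write a mosaic slide to disk as tiles plus a manifest
#'
#' The mosaic directory layout — PNG tiles with a CSV manifest of offsets —
#' is the plain-text stand-in for a pyramidal whole-slide file.
#'
#' @param tiles list of raster arrays.
#' @param offsets data frame with columns `x0`, `y0` (pixel offsets).
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_mosaic <- function(tiles, offsets, dir) {
  stopifnot(length(tiles) == nrow(offsets))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("tile_%04d.png", seq_along(tiles))
  for (i in seq_along(tiles)) {
    png::writePNG(tiles[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files, x0 = offsets$x0, y0 = offsets$y0,
    w = vapply(tiles, function(t) dim(t)[2], numeric(1)),
    h = vapply(tiles, function(t) dim(t)[1], numeric(1))
  )
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a mosaic slide directory back into one raster
#'
#' @param dir directory written by [write_mosaic()].
#' @return Raster array `[y, x, 3]` of the assembled slide.
#' @export
read_mosaic <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop_invalid("mosaic manifest not found: %s", path)
  manifest <- read.csv(path)
  W <- max(manifest$x0 + manifest$w)
  H <- max(manifest$y0 + manifest$h)
  slide <- array(0, dim = c(H, W, 3))
  for (i in seq_len(nrow(manifest))) {
    img <- png::readPNG(file.path(dir, manifest$file[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    ys <- manifest$y0[i] + seq_len(manifest$h[i])
    xs <- manifest$x0[i] + seq_len(manifest$w[i])
    slide[ys, xs, ] <- img[, , 1:3]
  }
  slide
}
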