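# Detector contract and the rule-based reference detector.
#
# A detector is any function raster -> detections data frame
# (x0, y0, x1, y1, confidence), pure in its input, boxes within the tile.
# The shipped reference detector encodes the morphological cues of a
# neutrophil on H&E — a dark lobulated nucleus inside a lighter cytoplasm —
# as explicit scores, so the pipeline is exercised end to end without any
# trained weights. A trained model slots in through the same contract.

# detector scoring constants; co-designed with the synthetic palette
detector_opts <- function(border_margin = 8L) {
  list(
    nuc_thresh = 0.5, # nuclear mask: mean RGB below this
    min_area = 4L, # components below this are noise, not lobes
    link_frac = 0.29, # lobe grouping radius as fraction of scale
    ring_frac = 0.42, # cytoplasm annulus radius as fraction of scale
    pad_frac = 0.8, # minimum emitted box side as fraction of scale
    w_lobe = 0.30, w_area = 0.35, w_ann = 0.35,
    border_margin = as.integer(border_margin)
  )
}

#' Filter detections by confidence
#'
#' Keeps detections whose confidence is at least `threshold`, preserving
#' order. The default 0.5 is the operating point of the pipeline's
#' classifier stage.
#'
#' @param dets detections data frame (`x0`, `y0`, `x1`, `y1`, `confidence`).
#' @param threshold confidence threshold in `[0, 1]`.
#' @return The filtered detections.
#' @export
filter_by_confidence <- function(dets, threshold = 0.5) {
  stopifnot(is.data.frame(dets), "confidence" %in% names(dets))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 || threshold > 1) {
    stop_invalid("threshold must be a single value in [0, 1]")
  }
  dets[dets$confidence >= threshold, , drop = FALSE]
}

# shared core: detect in a rectangular region of a slide without copying it.
# rect is c(x0, y0, x1, y1) in slide coords; open_edges flags window edges
# that are interior cuts (candidates hugging them are left to a neighbour
# window). Returns detections in slide coordinates, descending confidence.
detect_region <- function(slide, rect, scale = 40,
                          open_edges = c(FALSE, FALSE, FALSE, FALSE),
                          opts = detector_opts()) {
  m <- detect_region_cpp(
    slide, dim(slide)[1], dim(slide)[2],
    as.integer(rect), scale, open_edges, opts
  )
  d <- as_detections(m)
  d[order(d$confidence, decreasing = TRUE), , drop = FALSE]
}

#' Rule-based reference neutrophil detector
#'
#' Segments nuclear material by darkness, labels connected components,
#' groups nearby components into candidate cells, and scores each candidate
#' on three morphological cues: lobe count (2–5 favoured), total nuclear
#' area relative to the expected cell area, and the presence of a lighter
#' cytoplasm annulus. The bounded weighted sum of the cues, clipped to
#' `[0, 1]`, is the confidence. Deterministic: identical tiles give
#' identical detections.
#'
#' @param tile colour raster array `[y, x, 3]` with values in `[0, 1]`.
#' @param scale expected target object side in pixels (default 40).
#' @return Detections data frame (`x0`, `y0`, `x1`, `y1`, `confidence`),
#'   sorted by descending confidence; boxes lie within the tile.
#' @examples
#' t <- generate_tile(tile_params(target_count = 2, seed = 7))
#' reference_detect(t$image)
#' @export
reference_detect <- function(tile, scale = 40) {
  if (!is.array(tile) || length(dim(tile)) != 3L || dim(tile)[3] < 3L) {
    stop_invalid("reference_detect needs a colour raster [y, x, 3]")
  }
  detect_region(tile, c(0L, 0L, dim(tile)[2], dim(tile)[1]), scale = scale)
}

#' Write detections to CSV
#'
#' @param dets detections data frame.
#' @param path output path.
#' @param image_id optional image identifier column value.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path, image_id = NULL) {
  out <- dets
  if (!is.null(image_id)) {
    ids <- if (nrow(out) == 0L) character(0) else rep_len(image_id, nrow(out))
    out <- cbind(image_id = ids, out)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write detections as normalized label lines with confidence appended
#'
#' One line per detection: `cls xc yc w h confidence`, coordinates
#' normalized to the image size — the label-file dialect extended with a
#' sixth confidence field.
#'
#' @param dets detections data frame.
#' @param image_w,image_h image dimensions in pixels.
#' @param path output path.
#' @param cls class index to write.
#' @return `path`, invisibly.
#' @export
write_detection_labels <- function(dets, image_w, image_h, path, cls = 0L) {
  lines <- if (nrow(dets) == 0L) {
    character(0)
  } else {
    nb <- to_normalized(dets[, c("x0", "y0", "x1", "y1")], image_w, image_h, cls)
    sprintf(
      "%d %.6f %.6f %.6f %.6f %.6f",
      nb$cls, nb$xc, nb$yc, nb$w, nb$h, dets$confidence
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read detections from CSV
#'
#' @param path CSV written by [write_detections()].
#' @return Detections data frame (with `image_id` column if present).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_invalid("detections file not found: %s", path)
  d <- read.csv(path)
  need <- c("x0", "y0", "x1", "y1", "confidence")
  if (!all(need %in% names(d))) {
    stop_invalid("detections file lacks columns: %s", paste(setdiff(need, names(d)), collapse = ", "))
  }
  d
}
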