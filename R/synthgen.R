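# Synthetic H&E-like fixture generator. Tiles emulate scanned histology at
# the working scale of the pipeline: a 224 x 224 px patch standing for one
# (rescaled) high-powered field, neutrophils ~40 x 40 px with a dark
# lobulated nucleus inside a lighter cytoplasm disc, among unlabelled
# distractor cells. Everything is a pure function of its parameters and seed.

# stain palette (RGB in [0,1]); values chosen so nuclear material sits below
# the detector's darkness threshold and cytoplasm is bluer than stroma
.palette <- list(
  background = c(0.91, 0.82, 0.86),
  cytoplasm = c(0.80, 0.69, 0.85),
  nucleus = c(0.33, 0.24, 0.47),
  lymph_nucleus = c(0.30, 0.26, 0.50),
  lymph_rim = c(0.78, 0.72, 0.86),
  rbc = c(0.93, 0.58, 0.60),
  necrotic = c(0.36, 0.31, 0.39)
)

#' Parameters for one synthetic tile
#'
#' @param tile_w,tile_h tile dimensions in pixels.
#' @param target_count number of neutrophils to plant.
#' @param target_size nominal neutrophil box side in pixels (>= 8).
#' @param distractor_counts named counts of unlabelled distractors:
#'   `lymphocyte` (single round dark nucleus), `rbc` (anucleate pink disc),
#'   `necrotic_fragment` (irregular dark speck cluster).
#' @param background_tint background RGB triple in `[0, 1]`.
#' @param noise_sd standard deviation of the achromatic intensity noise.
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical output.
#' @return A `tile_params` list.
#' @export
tile_params <- function(tile_w = 224L, tile_h = 224L, target_count = 4L,
                        target_size = 40L,
                        distractor_counts = c(lymphocyte = 3L, rbc = 10L, necrotic_fragment = 2L),
                        background_tint = .palette$background,
                        noise_sd = 0.025, seed = 1L) {
  stopifnot(
    is_count(tile_w), is_count(tile_h), is_count(target_count),
    is_count(target_size), target_size >= 8L,
    all(distractor_counts >= 0), length(background_tint) == 3L,
    noise_sd >= 0, is_count(seed)
  )
  dc <- c(lymphocyte = 0L, rbc = 0L, necrotic_fragment = 0L)
  dc[names(distractor_counts)] <- as.integer(distractor_counts)
  structure(
    list(
      tile_w = as.integer(tile_w), tile_h = as.integer(tile_h),
      target_count = as.integer(target_count),
      target_size = as.integer(target_size),
      distractor_counts = dc,
      background_tint = as.numeric(background_tint),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "tile_params"
  )
}

# palette in the fixed row order the C++ planner expects
palette_matrix <- function() {
  rbind(
    .palette$cytoplasm, .palette$nucleus, .palette$lymph_rim,
    .palette$lymph_nucleus, .palette$rbc, .palette$necrotic
  )
}

#' Generate one synthetic tile with ground truth
#'
#' Plants `target_count` neutrophils (rejection-sampled so no two
#' ground-truth boxes overlap with IOU above 0.3) plus unlabelled
#' distractors, renders them onto the background, and adds noise. The
#' ground-truth box of each neutrophil is the `target_size` square centred
#' on the cell.
#'
#' @param p a [tile_params()] object.
#' @param image_id identifier for the annotation set.
#' @param min_dist optional minimum centre-to-centre distance between
#'   targets, beyond the IOU rule (used for well-separated fixtures).
#' @param with_labels build the [annotation_set()] (skipped in bulk paths
#'   that only need pixel truth).
#' @return List with `image` (array `[y, x, 3]`), `labels`
#'   ([annotation_set()] or `NULL`), and `truth` (pixel-box data frame).
#' @export
generate_tile <- function(p, image_id = sprintf("tile_%d", p$seed),
                          min_dist = NULL, with_labels = TRUE) {
  stopifnot(inherits(p, "tile_params"))
  res <- generate_tile_cpp(
    p$seed, derive_seed(p$seed, 777L),
    p$tile_w, p$tile_h, p$target_count, p$target_size,
    as.integer(p$distractor_counts), palette_matrix(),
    p$background_tint, p$noise_sd,
    if (is.null(min_dist)) 0 else min_dist
  )
  centres <- res$centres
  half <- p$target_size / 2
  truth <- data.frame(
    x0 = centres[, 1] - half, y0 = centres[, 2] - half,
    x1 = centres[, 1] + half, y1 = centres[, 2] + half
  )
  labels <- NULL
  if (with_labels) {
    labels <- annotation_set(
      image_id, p$tile_w, p$tile_h,
      if (nrow(truth)) to_normalized(truth, p$tile_w, p$tile_h, 0L) else
        normalized_box(0L, 0.5, 0.5, 1, 1)[0, ]
    )
  }
  list(image = res$image, labels = labels, truth = truth)
}

#' Parameters for one synthetic case (slide)
#'
#' Per-HPF neutrophil counts follow a negative binomial whose mean depends
#' on infection status; the overdispersion mirrors the clustered "hot spot"
#' distribution of neutrophils in inflamed periprosthetic tissue.
#'
#' @param case_id identifier.
#' @param infected logical true infection status.
#' @param n_hpf number of high-powered-field tiles in the case.
#' @param mean_count_infected,mean_count_sterile negative-binomial means of
#'   the per-HPF neutrophil count (defaults 8 and 2, straddling the
#'   diagnostic threshold of 5).
#' @param count_dispersion negative-binomial size parameter (smaller =
#'   more clustered; default 3).
#' @param tile template [tile_params()] for the rendered tiles.
#' @param seed integer seed.
#' @return A `case_params` list.
#' @export
case_params <- function(case_id, infected, n_hpf = 200L,
                        mean_count_infected = 8, mean_count_sterile = 2,
                        count_dispersion = 3, tile = tile_params(), seed = 1L) {
  stopifnot(
    length(case_id) == 1L, is.logical(infected), length(infected) == 1L,
    is_count(n_hpf), n_hpf >= 1L, count_dispersion > 0,
    mean_count_infected > mean_count_sterile,
    inherits(tile, "tile_params"), is_count(seed)
  )
  structure(
    list(
      case_id = as.character(case_id), infected = infected,
      n_hpf = as.integer(n_hpf),
      mean_count_infected = mean_count_infected,
      mean_count_sterile = mean_count_sterile,
      count_dispersion = count_dispersion,
      tile = tile, seed = as.integer(seed)
    ),
    class = "case_params"
  )
}

# per-HPF true counts for a case: NB(mu, size) under the case seed
draw_case_counts <- function(p) {
  mu <- if (p$infected) p$mean_count_infected else p$mean_count_sterile
  withr::with_seed(
    derive_seed(p$seed, 0L),
    rnbinom(p$n_hpf, size = p$count_dispersion, mu = mu)
  )
}

#' Generate a synthetic case bundle
#'
#' Draws the per-HPF neutrophil counts from the case's count distribution,
#' then materializes each HPF tile via [generate_tile()] with a sub-seed
#' derived from the case seed and tile index.
#'
#' @param p a [case_params()] object.
#' @param materialize if `FALSE`, skip rendering and return counts only.
#' @return A `case_bundle`: `case_id`, `infected`, `true_counts`, and (when
#'   materialized) `tiles`, a list of [generate_tile()] results.
#' @export
generate_case <- function(p, materialize = TRUE) {
  stopifnot(inherits(p, "case_params"))
  counts <- draw_case_counts(p)
  tiles <- NULL
  if (materialize) {
    tiles <- lapply(seq_len(p$n_hpf), function(i) {
      tp <- p$tile
      tp$target_count <- counts[i]
      tp$seed <- derive_seed(p$seed, i)
      generate_tile(tp, image_id = sprintf("%s_hpf%04d", p$case_id, i))
    })
  }
  structure(
    list(
      case_id = p$case_id, infected = p$infected, params = p,
      true_counts = as.integer(counts), tiles = tiles
    ),
    class = "case_bundle"
  )
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf(
    "<case_bundle> %s (%s), %d HPFs, true median count %.1f\n",
    x$case_id, if (x$infected) "infected" else "sterile",
    length(x$true_counts), median(x$true_counts)
  ))
  invisible(x)
}

#' Generate a synthetic case as one mosaic slide
#'
#' Lays the case's HPF tiles out on a raster-order grid and streams each
#' rendered tile into a single slide array, the mosaic stand-in for a
#' pyramidal whole-slide image. Grid cells beyond `n_hpf` (when `n_hpf` is
#' not a multiple of the column count) are rendered as empty background.
#'
#' @param p a [case_params()] object.
#' @param ncol tiles per mosaic row; default near-square layout.
#' @return List with `slide` (array `[y, x, 3]`), `hpf_boxes` (pixel boxes
#'   of the `n_hpf` real tiles, raster order), `true_counts`, `truth`
#'   (ground-truth boxes in slide coordinates), `infected`, `case_id`.
#' @export
generate_case_mosaic <- function(p, ncol = NULL) {
  stopifnot(inherits(p, "case_params"))
  counts <- draw_case_counts(p)
  n <- p$n_hpf
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  tw <- p$tile$tile_w
  th <- p$tile$tile_h
  seeds <- vapply(seq_len(n), function(i) derive_seed(p$seed, i), integer(1))
  res <- render_case_cpp(
    as.numeric(seeds),
    as.numeric(vapply(seeds, derive_seed, integer(1), index = 777L)),
    as.integer(counts), as.integer(ncol), tw, th,
    p$tile$target_size, as.integer(p$tile$distractor_counts),
    palette_matrix(), p$tile$background_tint, p$tile$noise_sd, 0
  )
  ix <- (seq_len(n) - 1L) %% ncol
  iy <- (seq_len(n) - 1L) %/% ncol
  truth <- as.data.frame(res$truth)
  truth$hpf <- res$hpf
  list(
    slide = res$slide,
    hpf_boxes = data.frame(
      x0 = ix * tw, y0 = iy * th, x1 = (ix + 1L) * tw, y1 = (iy + 1L) * th
    ),
    true_counts = as.integer(counts),
    truth = truth, infected = p$infected, case_id = p$case_id
  )
}

#' Split a dataset into train/validation/test partitions
#'
#' Seeded random permutation partitioned as `floor(f1 * n)`,
#' `floor(f2 * n)`, remainder — the scheme that turns 3,923 items at
#' 70/20/10 into 2,746 / 784 / 393.
#'
#' @param n_items number of items (IDs are `1:n_items`).
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed for the permutation.
#' @return List of integer id vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_items, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(is_count(n_items), is_count(seed))
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1)) {
    stop_invalid("fractions must be three values in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("fractions must sum to 1 (got %.9f)", sum(fractions))
  }
  if (n_items == 0L) {
    return(list(train = integer(0), val = integer(0), test = integer(0)))
  }
  perm <- withr::with_seed(seed, sample.int(n_items))
  n1 <- floor(fractions[1] * n_items)
  n2 <- floor(fractions[2] * n_items)
  list(
    train = perm[seq_len(n1)],
    val = perm[n1 + seq_len(n2)],
    test = perm[seq.int(n1 + n2 + 1, length.out = n_items - n1 - n2)]
  )
}
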