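# End-to-end pipeline drivers tying the stages together: synthetic slide ->
# window plan -> detector -> cross-window merge -> confidence filter ->
# HPF counting -> median -> diagnosis.

#' Run the detection-to-diagnosis pipeline on one synthetic case
#'
#' Renders the case as a mosaic slide, detects neutrophils through the
#' sliding-window plan, filters at the confidence threshold, counts
#' detections per HPF tile, and classifies the case from the median count.
#' The synthetic tiles are already at HPF scale, so the HPF grid side
#' equals the tile side.
#'
#' @param p a [case_params()] object.
#' @param window,overlap sliding-window geometry.
#' @param confidence_threshold detection confidence cut (default 0.5).
#' @param threshold,rule diagnosis rule (see [classify_case()]).
#' @param dedup_iou cross-window duplicate-suppression IOU.
#' @return List with `case_id`, `infected` (truth), `predicted`,
#'   `hpf_counts` (measured), `true_counts`, `median`, `record`.
#' @export
run_case_pipeline <- function(p, window = 512L, overlap = 0.3,
                              confidence_threshold = 0.5,
                              threshold = 5, rule = "ge", dedup_iou = 0.5) {
  stopifnot(inherits(p, "case_params"))
  mosaic <- generate_case_mosaic(p)
  dets <- detect_slide(mosaic$slide,
    window = window, overlap = overlap,
    scale = p$tile$target_size, dedup_iou = dedup_iou
  )
  dets <- filter_by_confidence(dets, confidence_threshold)
  grid <- make_hpf_grid(dim(mosaic$slide)[2], dim(mosaic$slide)[1],
    side = p$tile$tile_w
  )
  counts_all <- count_by_hpf(dets, grid)
  # grid cells beyond n_hpf are background padding, not part of the case
  counts <- counts_all[seq_len(p$n_hpf)]
  record <- summarize_case(p$case_id, counts)
  list(
    case_id = p$case_id, infected = mosaic$infected,
    predicted = classify_case(record$median, threshold, rule),
    hpf_counts = counts, true_counts = mosaic$true_counts,
    median = record$median, record = record
  )
}

#' Simulate a cohort and recover diagnoses through the full pipeline
#'
#' Generates `n_cases` synthetic cases (half infected, half sterile by
#' default), runs [run_case_pipeline()] on each, and tabulates predicted
#' against true infection status — the parameter-recovery experiment for
#' the whole imaging-and-diagnosis chain.
#'
#' @param n_cases number of cases.
#' @param n_infected number of infected cases (default half).
#' @param n_hpf HPFs per case.
#' @param seed cohort seed; per-case seeds are derived from it.
#' @param tile template [tile_params()].
#' @param ... passed to [run_case_pipeline()].
#' @return Data frame with one row per case: `case_id`, `infected`,
#'   `predicted`, `correct`, `median_detected`, `median_true`.
#' @export
simulate_cohort <- function(n_cases = 20L, n_infected = n_cases %/% 2L,
                            n_hpf = 200L, seed = 1L, tile = tile_params(), ...) {
  stopifnot(is_count(n_cases), n_infected <= n_cases)
  rows <- lapply(seq_len(n_cases), function(i) {
    p <- case_params(
      case_id = sprintf("sim%02d", i),
      infected = i <= n_infected, n_hpf = n_hpf,
      tile = tile, seed = derive_seed(seed, 7000L + i)
    )
    r <- run_case_pipeline(p, ...)
    data.frame(
      case_id = r$case_id,
      infected = r$infected,
      predicted = r$predicted,
      correct = (r$predicted == "infected") == r$infected,
      median_detected = r$median,
      median_true = median(r$true_counts)
    )
  })
  do.call(rbind, rows)
}
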