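test_that("match_detections handles identity, empty, and claimed-truth cases", {
  truths <- as_box_df(c(0, 0, 10, 10))
  same <- dets_df(rbind(c(0, 0, 10, 10)), 0.9)
  m <- match_detections(same, truths)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))

  none <- match_detections(empty_detections_for_test(), truths)
  expect_equal(c(none$tp, none$fp, none$fn), c(0L, 0L, 1L))

  # second detection overlaps well but the truth is already claimed
  d2 <- dets_df(rbind(c(0, 0, 10, 10), c(1, 1, 11, 11)), c(0.9, 0.8))
  m2 <- match_detections(d2, truths)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(m2$matched_pairs$det, 1L)
})

test_that("matching conserves counts and is monotone in the IOU threshold", {
  withr::with_seed(81, {
    for (rep in 1:30) {
      nt <- sample(0:6, 1)
      nd <- sample(0:6, 1)
      truths <- if (nt) do.call(rbind, lapply(1:nt, function(i) as_box_df(random_int_box()))) else as_box_df(c(0, 0, 1, 1))[0, ]
      dets <- if (nd) {
        dets_df(
          do.call(rbind, lapply(1:nd, function(i) random_int_box())),
          runif(nd)
        )
      } else {
        empty_detections_for_test()
      }
      m <- match_detections(dets, truths)
      expect_equal(m$tp + m$fn, nt)
      expect_equal(m$tp + m$fp, nd)
      tps <- vapply(
        c(0.25, 0.5, 0.75),
        function(t) match_detections(dets, truths, t)$tp, numeric(1)
      )
      expect_true(all(diff(tps) <= 0))
    }
  })
})

test_that("greedy matching equals exhaustive maximum matching on small instances", {
  withr::with_seed(82, {
    for (rep in 1:60) {
      nt <- sample(1:6, 1)
      nd <- sample(1:6, 1)
      truths <- do.call(rbind, lapply(1:nt, function(i) {
        x0 <- runif(1, 0, 50)
        y0 <- runif(1, 0, 50)
        as_box_df(c(x0, y0, x0 + runif(1, 5, 25), y0 + runif(1, 5, 25)))
      }))
      dets <- dets_df(do.call(rbind, lapply(1:nd, function(i) {
        x0 <- runif(1, 0, 50)
        y0 <- runif(1, 0, 50)
        c(x0, y0, x0 + runif(1, 5, 25), y0 + runif(1, 5, 25))
      })), runif(nd))
      m <- iou_matrix(dets, truths)
      # continuous coordinates: ties at the threshold have measure zero
      expect_equal(
        match_detections(dets, truths)$tp,
        exhaustive_max_tp(m, 0.5)
      )
    }
  })
})

test_that("detection_metrics reproduces report values and flags degeneracy", {
  m <- detection_metrics(101, 22, 27)
  expect_equal(rhu(m$precision, 2), 0.82)
  expect_equal(rhu(m$recall, 2), 0.79)
  expect_equal(rhu(m$f1, 2), 0.80)

  m2 <- detection_metrics(9, 1, 2)
  expect_equal(rhu(m2$precision, 2), 0.90)
  expect_equal(rhu(m2$recall, 2), 0.82)
  expect_equal(rhu(m2$f1, 2), 0.86)

  z <- detection_metrics(0, 0, 0)
  expect_true(all(is.na(c(z$precision, z$recall, z$f1))))
  expect_false(any(z$defined))

  # F1 lies between precision and recall on random counts
  withr::with_seed(83, {
    for (rep in 1:20) {
      e <- detection_metrics(sample(1:50, 1), sample(0:20, 1), sample(0:20, 1))
      expect_gte(e$f1, min(e$precision, e$recall) - 1e-12)
      expect_lte(e$f1, max(e$precision, e$recall) + 1e-12)
    }
  })
})

test_that("confidence_precision_curve tracks the filtered sets", {
  truths <- rbind(as_box_df(c(0, 0, 20, 20)), as_box_df(c(50, 50, 70, 70)))
  # true hits at high confidence, noisy extras strictly lower
  dets <- dets_df(rbind(
    c(0, 0, 20, 20), c(50, 50, 70, 70),
    c(100, 100, 120, 120), c(140, 10, 160, 30)
  ), c(0.9, 0.8, 0.4, 0.3))
  curve <- confidence_precision_curve(dets, truths, thresholds = c(0, 0.35, 0.5, 0.85))
  unfiltered <- detection_metrics(match_detections(dets, truths))
  expect_equal(curve$precision[1], unfiltered$precision)
  expect_equal(curve$precision, c(0.5, 2 / 3, 1, 1))
  expect_true(all(diff(curve$precision) >= 0))
  # everything filtered out: precision undefined, not silently 1 or 0
  empty_tail <- confidence_precision_curve(dets, truths, thresholds = 0.95)
  expect_true(is.na(empty_tail$precision))

  perfect <- dets_df(rbind(c(0, 0, 20, 20), c(50, 50, 70, 70)), c(0.9, 0.6))
  pc <- confidence_precision_curve(perfect, truths, thresholds = c(0, 0.5))
  expect_equal(pc$precision, c(1, 1))
})

test_that("interobserver metrics follow the matched-pair formulas", {
  px <- do.call(rbind, lapply(0:4, function(i) as_box_df(c(i * 30, 0, i * 30 + 20, 20))))
  b <- annot_from_pixels("img", 300, 300, px)
  expect_equal(interobserver_metrics(b, b)$f1, 1)

  disjoint <- annot_from_pixels("img", 300, 300, as_box_df(c(0, 100, 20, 120)))
  z <- interobserver_metrics(disjoint, b)
  expect_equal(c(z$precision, z$recall), c(0, 0))

  # |a| = 4, |b| = 5, 3 pairs above threshold
  a_px <- rbind(
    px[1:3, ] + 2, # three near-copies, IOU ~ 0.68
    as_box_df(c(200, 200, 220, 220))
  )
  a <- annot_from_pixels("img", 300, 300, a_px)
  m <- interobserver_metrics(a, b)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-9)
})

test_that("evaluate_detections pools per-image counts and checks ids", {
  truths <- list(
    img1 = as_box_df(c(0, 0, 20, 20)),
    img2 = rbind(as_box_df(c(0, 0, 20, 20)), as_box_df(c(40, 40, 60, 60)))
  )
  dets <- list(
    img1 = dets_df(rbind(c(0, 0, 20, 20)), 0.9),
    img2 = dets_df(rbind(c(1, 1, 21, 21), c(100, 100, 120, 120)), c(0.8, 0.7))
  )
  r <- evaluate_detections(dets, truths)
  expect_equal(r$pooled$tp, 2L)
  expect_equal(r$pooled$fp, 1L)
  expect_equal(r$pooled$fn, 1L)
  expect_error(evaluate_detections(dets["img1"], truths), "mismatch")
})
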