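test_that("hpf_side converts calibration to pixels", {
  expect_equal(hpf_side(calibration(4050, 0.2)), 1811L)
  expect_equal(hpf_side(calibration(1000, 1)), 1000L)
  expect_equal(hpf_side(calibration(4050, 0.05)), 906L)
})

test_that("make_hpf_grid tiles with truncation and conserves area", {
  g1 <- make_hpf_grid(1811, 1811)
  expect_equal(nrow(g1$tiles), 1L)
  g6 <- make_hpf_grid(4000, 2000, side = 1811L)
  expect_equal(nrow(g6$tiles), 6L)
  expect_equal(max(g6$tiles$x1), 4000)
  expect_equal(max(g6$tiles$y1), 2000)
  gmin <- make_hpf_grid(1, 1)
  expect_equal(unlist(gmin$tiles[1, ]), c(x0 = 0, y0 = 0, x1 = 1, y1 = 1))

  withr::with_seed(71, {
    for (rep in 1:20) {
      w <- sample.int(5000, 1)
      h <- sample.int(5000, 1)
      side <- sample(50:2000, 1)
      g <- make_hpf_grid(w, h, side = side)
      expect_equal(nrow(g$tiles), ceiling(w / side) * ceiling(h / side))
      areas <- (g$tiles$x1 - g$tiles$x0) * (g$tiles$y1 - g$tiles$y0)
      expect_equal(sum(areas), as.numeric(w) * h) # exact area conservation
      m <- iou_matrix(g$tiles, g$tiles)
      diag(m) <- 0
      expect_true(all(m == 0)) # pairwise non-overlapping
    }
  })
})

test_that("plan_windows strides and clamps as specified", {
  p1 <- plan_windows(512, 512)
  expect_equal(nrow(p1$windows), 1L)
  p3 <- plan_windows(1024, 512)
  expect_equal(p3$stride, 358L)
  expect_equal(sort(unique(p3$windows$x0)), c(0, 358, 512))
  expect_equal(nrow(p3$windows), 3L)
  p0 <- plan_windows(1024, 512, overlap = 0)
  expect_equal(sort(unique(p0$windows$x0)), c(0, 512))
  expect_error(plan_windows(100, 100, overlap = 1), "\\[0, 1\\)")
})

test_that("window plans cover every pixel, twice per axis in the interior", {
  withr::with_seed(72, {
    for (rep in 1:25) {
      w <- sample.int(3000, 1)
      h <- sample.int(3000, 1)
      p <- plan_windows(w, h)
      # per-axis pixel coverage audit
      for (axis in 1:2) {
        dim_len <- if (axis == 1) w else h
        lo <- if (axis == 1) p$windows$x0 else p$windows$y0
        hi <- if (axis == 1) p$windows$x1 else p$windows$y1
        cov <- integer(dim_len)
        for (k in seq_along(lo)) {
          cov[(lo[k] + 1):hi[k]] <- cov[(lo[k] + 1):hi[k]] + 1L
        }
        expect_true(all(cov >= 1L))
        expect_true(all(hi <= dim_len))
      }
    }
  })
  # adjacent windows overlap by at least overlap * window along each axis
  p <- plan_windows(2000, 512)
  offs <- sort(unique(p$windows$x0))
  overlaps <- offs[-length(offs)] + 512 - offs[-1]
  expect_true(all(overlaps >= floor(0.3 * 512)))
})

test_that("merge_window_detections translates, dedups, and is idempotent", {
  plan <- plan_windows(1024, 512)
  # single window: pure translation
  one <- list(dets_df(rbind(c(10, 10, 50, 50)), 0.8), NULL, NULL)
  m1 <- merge_window_detections(one, plan)
  expect_equal(unlist(m1[1, 1:4]), c(x0 = 10, y0 = 10, x1 = 50, y1 = 50))

  # same object in two overlapping windows: keep the higher confidence
  obj_slide <- c(400, 100, 440, 140)
  w1 <- plan$windows[1, ] # x0 = 0
  w2_idx <- which(plan$windows$x0 == 358)[1]
  w2 <- plan$windows[w2_idx, ]
  per <- vector("list", nrow(plan$windows))
  per[[1]] <- dets_df(rbind(obj_slide - c(w1$x0, w1$y0, w1$x0, w1$y0)), 0.9)
  per[[w2_idx]] <- dets_df(rbind(obj_slide - c(w2$x0, w2$y0, w2$x0, w2$y0)), 0.7)
  m <- merge_window_detections(per, plan)
  expect_equal(nrow(m), 1L)
  expect_equal(m$confidence, 0.9)
  expect_equal(unlist(m[1, 1:4]), c(x0 = 400, y0 = 100, x1 = 440, y1 = 140))

  # distinct objects survive
  per[[w2_idx]] <- dets_df(rbind(c(10, 300, 50, 340)), 0.7)
  m2 <- merge_window_detections(per, plan)
  expect_equal(nrow(m2), 2L)

  # idempotence: merging the merged output changes nothing
  plan_id <- plan_windows(1024, 512, overlap = 0)
  again <- merge_window_detections(
    list(m2[m2$x0 < 512, ], transform(m2[m2$x0 >= 512, ],
      x0 = x0 - 512, x1 = x1 - 512
    )),
    plan_id
  )
  expect_equal(nrow(again), 2L)

  # out-of-window detections are rejected
  bad <- vector("list", nrow(plan$windows))
  bad[[1]] <- dets_df(rbind(c(500, 0, 600, 40)), 0.5)
  expect_error(merge_window_detections(bad, plan), "outside")
})

test_that("planting k separated targets yields exactly k merged detections", {
  hits <- vapply(1:100, function(s) {
    k <- (s - 1) %% 4 + 1
    g <- generate_tile(
      tile_params(
        tile_w = 600L, tile_h = 600L, target_count = k,
        distractor_counts = c(lymphocyte = 2, rbc = 6, necrotic_fragment = 1),
        seed = 5000 + s
      ),
      min_dist = 60, with_labels = FALSE
    )
    d <- filter_by_confidence(detect_slide(g$image), 0.5)
    m <- match_detections(d, g$truth)
    m$tp == k && m$fp == 0L
  }, logical(1))
  expect_true(all(hits))
})

test_that("count_by_hpf assigns centres with lower-index tie break", {
  grid <- make_hpf_grid(448, 448, side = 224L)
  d <- dets_df(rbind(
    c(10, 10, 50, 50), # tile 1
    c(300, 10, 340, 50), # tile 2
    c(204, 100, 244, 140) # centre exactly on the boundary -> tile 1
  ), c(0.9, 0.9, 0.9))
  expect_equal(count_by_hpf(d, grid), c(2L, 1L, 0L, 0L))
  expect_equal(count_by_hpf(empty_detections_for_test(), grid), integer(4))
})

test_that("mosaic write/read round trip preserves the slide", {
  p <- case_params("m", infected = FALSE, n_hpf = 4L, seed = 12)
  b <- generate_case(p)
  dir <- withr::local_tempdir()
  offs <- data.frame(x0 = c(0, 224, 0, 224), y0 = c(0, 0, 224, 224))
  write_mosaic(lapply(b$tiles, `[[`, "image"), offs, dir)
  slide <- read_mosaic(dir)
  expect_equal(dim(slide), c(448, 448, 3))
  # PNG quantizes to 8 bits; agreement to within one grey level
  expect_equal(slide[1:224, 1:224, ], b$tiles[[1]]$image, tolerance = 1 / 255)
})
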