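test_that("read_labels parses lines and validates coordinates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.2", f)
  a <- read_labels(f, 100, 100)
  expect_equal(nrow(a$boxes), 1L)
  expect_equal(
    unlist(from_normalized(a$boxes, 100, 100)),
    c(x0 = 40, y0 = 40, x1 = 60, y1 = 60)
  )

  writeLines(character(0), f)
  expect_equal(nrow(read_labels(f, 100, 100)$boxes), 0L)

  writeLines(c("0 0.5 0.5 0.2 0.2", "0 1.5 0.5 0.2 0.2"), f)
  expect_error(read_labels(f, 100, 100), "line 2")
  writeLines("0 0.5 0.5 0.2", f)
  expect_error(read_labels(f, 100, 100), "5 fields")
  writeLines("0 a 0.5 0.2 0.2", f)
  expect_error(read_labels(f, 100, 100), "non-numeric")
})

test_that("label round trip is lossless to 6 decimals and preserves cardinality", {
  f <- withr::local_tempfile(fileext = ".txt")
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(0:6, 1)
      boxes <- if (n == 0) {
        normalized_box(0, 0.5, 0.5, 1, 1)[0, ]
      } else {
        do.call(rbind, lapply(seq_len(n), function(i) {
          w <- runif(1, 0.05, 0.3)
          h <- runif(1, 0.05, 0.3)
          normalized_box(
            0, runif(1, w / 2, 1 - w / 2), runif(1, h / 2, 1 - h / 2), w, h
          )
        }))
      }
      a <- annotation_set("img", 224, 224, boxes)
      write_labels(a, f)
      if (n == 0) expect_identical(file.size(f), 0) # empty set -> empty file
      back <- read_labels(f, 224, 224)
      expect_equal(nrow(back$boxes), n)
      expect_equal(length(readLines(f, warn = FALSE)), n)
      if (n > 0) {
        expect_equal(as.matrix(back$boxes), as.matrix(boxes), tolerance = 1e-6)
      }
    }
  })
})

test_that("rescale_annotated scales pixels but not normalized values", {
  img <- array(runif(640 * 480 * 3), dim = c(480, 640, 3))
  a <- annotation_set(
    "img", 640, 480,
    to_normalized(box(100, 100, 140, 140), 640, 480)
  )
  # shrink until the image is 80 px tall (the working scale for ~40 px cells)
  out <- rescale_annotated(img, a, 80 / 480)
  expect_equal(dim(out$image)[1:2], c(80, 107))
  expect_equal(out$labels$image_w, 107L)
  expect_equal(as.matrix(out$labels$boxes), as.matrix(a$boxes))
  # a 40 px box at factor 0.5 becomes 20 px in pixel space
  half <- rescale_annotated(img, a, 0.5)
  pb <- from_normalized(half$labels$boxes, half$labels$image_w, half$labels$image_h)
  expect_equal(pb$x1 - pb$x0, 20)

  ident <- rescale_annotated(img, a, 1)
  expect_identical(ident$image, img)
  expect_equal(ident$labels$boxes, a$boxes)
  expect_error(rescale_annotated(img, a, 0.001), "degenerate")
  expect_error(rescale_annotated(img, a, -1), "positive")
})

test_that("consensus_merge agrees, disputes, and conserves boxes", {
  px_a <- as_box_df(c(10, 10, 50, 50))
  a <- annot_from_pixels("img", 224, 224, px_a)
  expect_s3_class(consensus_merge(a, a), "consensus_report")
  same <- consensus_merge(a, a)
  expect_equal(nrow(same$agreed), 1L)
  expect_equal(nrow(same$disputed_a_only), 0L)

  empty <- annotation_set("img", 224, 224)
  one_sided <- consensus_merge(a, empty)
  expect_equal(nrow(one_sided$agreed), 0L)
  expect_equal(nrow(one_sided$disputed_a_only), 1L)

  # IOU 64/136 < 0.5: no agreement
  b <- annot_from_pixels(
    "img", 224, 224,
    rbind(as_box_df(c(2, 2, 12, 12)), as_box_df(c(50, 50, 60, 60)))
  )
  a1 <- annot_from_pixels("img", 224, 224, as_box_df(c(0, 0, 10, 10)))
  r <- consensus_merge(a1, b)
  expect_equal(nrow(r$agreed), 0L)
  expect_equal(nrow(r$disputed_a_only), 1L)
  expect_equal(nrow(r$disputed_b_only), 2L)

  expect_error(consensus_merge(a, annotation_set("img", 100, 100)), "dimensions differ")
})

test_that("consensus_merge is symmetric and conserves counts on random sets", {
  withr::with_seed(22, {
    for (rep in 1:20) {
      na <- sample(0:6, 1)
      nb <- sample(0:6, 1)
      mk <- function(n) {
        if (n == 0) {
          return(annotation_set("img", 300, 300))
        }
        px <- do.call(rbind, lapply(seq_len(n), function(i) {
          x0 <- sample.int(250, 1)
          y0 <- sample.int(250, 1)
          as_box_df(c(x0, y0, x0 + sample(10:40, 1), y0 + sample(10:40, 1)))
        }))
        annot_from_pixels("img", 300, 300, px)
      }
      a <- mk(na)
      b <- mk(nb)
      r <- consensus_merge(a, b)
      expect_equal(
        2 * nrow(r$agreed) + nrow(r$disputed_a_only) + nrow(r$disputed_b_only),
        na + nb
      )
      r2 <- consensus_merge(b, a)
      expect_equal(nrow(r2$agreed), nrow(r$agreed))
      expect_equal(nrow(r2$disputed_a_only), nrow(r$disputed_b_only))
    }
  })
})

test_that("exclude_boxes strikes rows like an expert exclusion list", {
  px <- rbind(as_box_df(c(0, 0, 10, 10)), as_box_df(c(20, 20, 40, 40)), as_box_df(c(50, 50, 70, 70)))
  a <- annot_from_pixels("img", 100, 100, px)
  expect_equal(nrow(exclude_boxes(a, 2)$boxes), 2L)
  expect_identical(exclude_boxes(a, integer(0)), a)
  expect_error(exclude_boxes(a, 4), "out of range")
})
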