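test_that("summarize_case computes order statistics and validates input", {
  r0 <- summarize_case("z", rep(0L, 10))
  expect_equal(c(r0$median, r0$q1, r0$q3), c(0, 0, 0))
  expect_equal(summarize_case("a", c(1, 2, 3, 4, 100))$median, 3)
  expect_equal(summarize_case("a", c(1, 2, 3, 4, 100))$n_patches, 5L)
  expect_error(summarize_case("e", integer(0)), "no HPF counts")
  expect_error(summarize_case("e", c(1, -2)), "non-negative")
})

test_that("an infected synthetic case at study scale has median >= 5", {
  b <- generate_case(case_params("big", TRUE, n_hpf = 339L, seed = 1),
    materialize = FALSE
  )
  expect_gte(summarize_case("big", b$true_counts)$median, 5)
})

test_that("classify_case applies the threshold rule", {
  expect_equal(classify_case(167), "infected")
  expect_equal(classify_case(5), "infected") # >= rule: median 5 is infected
  expect_equal(classify_case(5, rule = "gt"), "not_infected")
  expect_equal(classify_case(0), "not_infected")
  expect_equal(classify_case(c(7, 3)), c("infected", "not_infected"))
})

test_that("mcnemar_exact matches the closed form and enumeration", {
  expect_equal(mcnemar_exact(1, 2)$p_value, 1)
  expect_equal(mcnemar_exact(0, 0)$p_value, 1)
  expect_equal(mcnemar_exact(0, 8)$p_value, 2 * 0.5^8)
  # symmetry and b = c
  for (b in 0:6) {
    expect_equal(mcnemar_exact(b, b)$p_value, 1)
    for (cc in 0:6) {
      expect_equal(mcnemar_exact(b, cc)$p_value, mcnemar_exact(cc, b)$p_value)
    }
  }
  # full binomial enumeration for all b + c <= 12
  for (n in 0:12) {
    probs <- choose(n, 0:n) / 2^n
    for (b in 0:n) {
      cc <- n - b
      k <- min(b, cc)
      expect_equal(
        mcnemar_exact(b, cc)$p_value,
        min(1, 2 * sum(probs[seq_len(k + 1)]))
      )
    }
  }
})

test_that("confusion tables reproduce the bundled 19-case cohort blocks", {
  fit <- pji_cohort(example_cohort())
  expect_equal(sum(fit$cases$predicted == "infected"), 10L)
  expect_equal(sum(fit$cases$predicted == "not_infected"), 9L)

  h <- fit$confusions$histology
  expect_equal(h$table["infected", "infected"], 7L, ignore_attr = TRUE)
  expect_equal(h$table["infected", "not_infected"], 2L, ignore_attr = TRUE)
  expect_equal(h$table["infected", "uncertain"], 1L, ignore_attr = TRUE)
  expect_equal(h$table["not_infected", "infected"], 2L, ignore_attr = TRUE)
  expect_equal(h$table["not_infected", "not_infected"], 6L, ignore_attr = TRUE)
  expect_equal(h$excluded_uncertain, 2L)
  expect_equal(percent_metric_for_test(h$metrics), c(78, 78, 78))

  mi <- fit$confusions$microbiology
  expect_equal(as.vector(mi$table), c(8L, 1L, 2L, 8L))
  expect_equal(percent_metric_for_test(mi$metrics), c(80, 89, 84))

  md <- fit$confusions$mdt
  expect_equal(as.vector(md$table), c(9L, 2L, 1L, 7L))
  expect_equal(percent_metric_for_test(md$metrics), c(90, 82, 86))

  # paired comparisons: all three non-significant
  ps <- vapply(fit$mcnemar, `[[`, numeric(1), "p_value")
  expect_equal(unname(ps), c(1, 1, 1))
})

test_that("confusion totals equal cohort size and validate labels", {
  fit <- pji_cohort(example_cohort())
  for (s in names(fit$confusions)) {
    expect_equal(sum(fit$confusions[[s]]$table), 19L)
  }
  bad <- example_cohort()
  bad$mdt[3] <- "maybe"
  expect_error(pji_cohort(bad), "unknown mdt")
  nolab <- example_cohort()[, c("case_id", "median")]
  fitn <- pji_cohort(nolab)
  expect_length(fitn$confusions, 0L)
})

test_that("pji_cohort accepts case records plus references", {
  recs <- list(
    summarize_case("a", c(9, 9, 10, 12)),
    summarize_case("b", c(0, 1, 1, 2))
  )
  refs <- data.frame(case_id = c("a", "b"), mdt = c("infected", "not_infected"))
  fit <- pji_cohort(recs, refs)
  expect_equal(fit$cases$predicted, c("infected", "not_infected"))
  expect_equal(as.vector(fit$confusions$mdt$table), c(1L, 0L, 0L, 1L))
  expect_true(fit$low_n)
  expect_equal(predict(fit, c(4, 5, 6)), c("not_infected", "infected", "infected"))
})

test_that("cohort predictions recover generator truth from true counts", {
  correct <- 0L
  total <- 0L
  for (s in 1:50) {
    for (infected in c(TRUE, FALSE)) {
      b <- generate_case(
        case_params("x", infected, n_hpf = 100L, seed = 400 + 2 * s + infected),
        materialize = FALSE
      )
      pred <- classify_case(median(b$true_counts))
      correct <- correct + ((pred == "infected") == infected)
      total <- total + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("print and summary methods render without error", {
  fit <- pji_cohort(example_cohort())
  expect_output(print(fit), "19 cases")
  expect_output(summary(fit), "Per-case table")
  expect_output(print(fit$confusions$mdt), "precision")
  expect_output(print(mcnemar_exact(1, 2)), "exact p")
})
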