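# Case-level diagnosis: aggregate per-HPF neutrophil counts into medians,
# apply the histological infection threshold (>= 5 neutrophils per HPF by
# default), tabulate against the reference standards, and compare paired
# classifiers with the exact McNemar test.

.diag_levels <- c("infected", "not_infected")

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

#' Summarize one case's per-HPF counts
#'
#' Median and quartiles use the standard linear-interpolation definition
#' (quantile type 7); full precision is kept internally, display rounding
#' happens only in reports.
#'
#' @param case_id identifier.
#' @param hpf_counts integer vector of per-HPF neutrophil counts (>= 1
#'   value).
#' @return A `case_record` with `case_id`, `n_patches`, `median`, `q1`,
#'   `q3`, and the raw `hpf_counts`.
#' @export
summarize_case <- function(case_id, hpf_counts) {
  if (length(hpf_counts) == 0L) stop_invalid("case %s has no HPF counts", case_id)
  if (any(!is.finite(hpf_counts)) || any(hpf_counts < 0)) {
    stop_invalid("case %s: counts must be non-negative", case_id)
  }
  q <- unname(quantile(hpf_counts, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(
      case_id = as.character(case_id), n_patches = length(hpf_counts),
      median = q[2], q1 = q[1], q3 = q[3],
      hpf_counts = as.integer(hpf_counts)
    ),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s: %d patches, median %.1f (IQR %.1f to %.1f)\n",
    x$case_id, x$n_patches, x$median, x$q1, x$q3
  ))
  invisible(x)
}

#' Classify a case from its median per-HPF count
#'
#' The default rule calls a case infected when the median neutrophil count
#' reaches the threshold (`median >= 5`), the reading under which a median
#' of exactly 5 counts as infected; the strict `gt` rule (`median > 5`) is
#' available.
#'
#' @param median median neutrophil count per HPF (>= 0).
#' @param threshold diagnostic count threshold (default 5, the consensus
#'   histological criterion).
#' @param rule `"ge"` (default) or `"gt"`.
#' @return `"infected"` or `"not_infected"`.
#' @export
classify_case <- function(median, threshold = 5, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(median), all(median >= 0))
  hit <- if (rule == "ge") median >= threshold else median > threshold
  ifelse(hit, "infected", "not_infected")
}

#' Exact McNemar test from discordant pair counts
#'
#' Two-sided exact binomial form: with `b` and `c` the two discordant
#' counts, `p = min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c,
#' 1/2)`; `p = 1` when `b = c` (including the no-discordance case).
#'
#' @param b discordant count (first classifier positive only).
#' @param c discordant count (second classifier positive only).
#' @return A `mcnemar_result` with `b`, `c`, `p_value`.
#' @examples
#' mcnemar_exact(1, 2) # p = 1
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(is_count(b), is_count(c))
  n <- b + c
  p <- if (n == 0L) 1 else min(1, 2 * pbinom(min(b, c), n, 0.5))
  structure(
    list(b = as.integer(b), c = as.integer(c), p_value = p),
    class = "mcnemar_result"
  )
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf(
    "<mcnemar_result> discordant %d vs %d, exact p = %.4g\n",
    x$b, x$c, x$p_value
  ))
  invisible(x)
}

#' Confusion table of predictions against one reference standard
#'
#' Rows are the computer prediction, columns the reference. For histology
#' an `uncertain` column is carried in the table but excluded from the
#' metric computation when `exclude_uncertain` is set; for microbiology the
#' positive reference level is `growth`.
#'
#' @param cases cohort data frame with `predicted` plus the reference
#'   column.
#' @param reference `"histology"`, `"microbiology"`, or `"mdt"`.
#' @param exclude_uncertain drop `uncertain` reference cases from metrics
#'   (they stay visible in the table).
#' @return A `confusion_table`: `table` (prediction x reference matrix),
#'   `metrics` (an `eval_metrics`), discordant counts `b`, `c`, and
#'   `excluded_uncertain`.
#' @export
confusion_table <- function(cases, reference = c("histology", "microbiology", "mdt"),
                            exclude_uncertain = TRUE) {
  reference <- match.arg(reference)
  if (!reference %in% names(cases)) {
    stop_invalid("cases carry no '%s' reference labels", reference)
  }
  if (!"predicted" %in% names(cases)) stop_invalid("cases carry no predictions")
  ref <- normalize_label(cases[[reference]])
  pred <- normalize_label(cases$predicted)
  pos <- if (reference == "microbiology") "growth" else "infected"
  neg <- if (reference == "microbiology") "no_growth" else "not_infected"
  ref_levels <- c(pos, neg)
  if (reference == "histology" && any(ref == "uncertain")) {
    ref_levels <- c(ref_levels, "uncertain")
  }
  bad <- setdiff(unique(ref), c(ref_levels, "uncertain"))
  if (length(bad)) stop_invalid("unknown %s label(s): %s", reference, paste(bad, collapse = ", "))
  tab <- table(
    factor(pred, levels = .diag_levels),
    factor(ref, levels = ref_levels)
  )
  dimnames(tab) <- list(predicted = .diag_levels, reference = ref_levels)
  keep <- if (exclude_uncertain) ref != "uncertain" else rep(TRUE, length(ref))
  tp <- sum(pred == "infected" & ref == pos & keep)
  fp <- sum(pred == "infected" & ref != pos & keep)
  fn <- sum(pred == "not_infected" & ref == pos & keep)
  structure(
    list(
      table = unclass(tab), reference = reference,
      metrics = detection_metrics(tp, fp, fn),
      b = fp, c = fn,
      excluded_uncertain = sum(!keep)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> prediction vs %s", x$reference))
  if (x$excluded_uncertain > 0) {
    cat(sprintf(" (%d uncertain excluded from metrics)", x$excluded_uncertain))
  }
  cat("\n")
  print(x$table)
  m <- x$metrics
  cat(sprintf(
    "precision %s%% | recall %s%% | F1 %s%%\n",
    percent_metric(m$precision), percent_metric(m$recall), percent_metric(m$f1)
  ))
  invisible(x)
}

#' Fit the median-count infection classifier over a cohort
#'
#' The cohort-level entry point: takes per-case count summaries (either raw
#' per-HPF counts or precomputed medians) with their reference diagnoses,
#' applies the threshold rule to every median, and assembles the per-case
#' table, the confusion tables against each available reference standard,
#' and the exact McNemar comparison for each.
#'
#' @param cases either a data frame with columns `case_id`, `median` (plus
#'   optionally `n_patches`, `q1`, `q3`) and any of `histology`,
#'   `microbiology`, `mdt`; or a list of [summarize_case()] records plus a
#'   `references` data frame keyed by `case_id`.
#' @param references optional data frame of reference diagnoses
#'   (`case_id`, `histology`, `microbiology`, `mdt`) merged onto the cases.
#' @param threshold,rule see [classify_case()].
#' @param exclude_uncertain see [confusion_table()].
#' @return A `pji_cohort` object with methods `print`, `summary`, `plot`,
#'   and `predict`.
#' @examples
#' fit <- pji_cohort(example_cohort())
#' fit
#' @export
pji_cohort <- function(cases, references = NULL, threshold = 5,
                       rule = c("ge", "gt"), exclude_uncertain = TRUE) {
  rule <- match.arg(rule)
  if (is.list(cases) && !is.data.frame(cases) &&
    all(vapply(cases, inherits, logical(1), "case_record"))) {
    cases <- do.call(rbind, lapply(cases, function(r) {
      data.frame(
        case_id = r$case_id, n_patches = r$n_patches,
        median = r$median, q1 = r$q1, q3 = r$q3
      )
    }))
  }
  stopifnot(is.data.frame(cases), nrow(cases) >= 1L)
  if (!all(c("case_id", "median") %in% names(cases))) {
    stop_invalid("cases need at least case_id and median columns")
  }
  if (!is.null(references)) {
    cases <- merge(cases, references, by = "case_id", sort = FALSE)
  }
  tab <- cases
  tab$predicted <- classify_case(tab$median, threshold, rule)
  standards <- intersect(c("histology", "microbiology", "mdt"), names(tab))
  confusions <- lapply(standards, function(s) {
    confusion_table(tab, s, exclude_uncertain = exclude_uncertain)
  })
  names(confusions) <- standards
  mcnemar <- lapply(confusions, function(ct) mcnemar_exact(ct$b, ct$c))
  structure(
    list(
      cases = tab, threshold = threshold, rule = rule,
      exclude_uncertain = exclude_uncertain,
      confusions = confusions, mcnemar = mcnemar,
      low_n = nrow(tab) < 5L
    ),
    class = "pji_cohort"
  )
}

#' @export
print.pji_cohort <- function(x, ...) {
  sym <- if (x$rule == "ge") ">=" else ">"
  cat(sprintf(
    "Median-per-HPF infection classifier (infected when median %s %g)\n",
    sym, x$threshold
  ))
  cat(sprintf(
    "%d cases: %d classified infected, %d not infected\n",
    nrow(x$cases), sum(x$cases$predicted == "infected"),
    sum(x$cases$predicted == "not_infected")
  ))
  if (x$low_n) cat("note: fewer than 5 cases; tabulations are fragile\n")
  for (s in names(x$confusions)) {
    m <- x$confusions[[s]]$metrics
    cat(sprintf(
      "  vs %-12s precision %3s%% recall %3s%% F1 %3s%% | McNemar p = %.3g\n",
      s, percent_metric(m$precision), percent_metric(m$recall),
      percent_metric(m$f1), x$mcnemar[[s]]$p_value
    ))
  }
  invisible(x)
}

#' @export
summary.pji_cohort <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-case table:\n")
  tab <- x$cases
  tab$median <- round_half_up(tab$median, 1)
  print(tab, row.names = FALSE)
  cat("\n")
  for (s in names(x$confusions)) print(x$confusions[[s]])
  invisible(x)
}

#' Predict infection labels for new medians
#'
#' @param object a [pji_cohort()] fit.
#' @param newdata numeric vector of medians, or a data frame with a
#'   `median` column; defaults to the fitted cohort.
#' @param ... unused.
#' @return Character vector of labels.
#' @export
predict.pji_cohort <- function(object, newdata = NULL, ...) {
  med <- if (is.null(newdata)) {
    object$cases$median
  } else if (is.data.frame(newdata)) {
    newdata$median
  } else {
    newdata
  }
  classify_case(med, object$threshold, object$rule)
}

#' Plot a cohort's medians against the diagnostic threshold
#'
#' @param x a [pji_cohort()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pji_cohort <- function(x, ...) {
  tab <- x$cases
  ord <- order(tab$median, decreasing = TRUE)
  tab <- tab[ord, ]
  col <- ifelse(tab$predicted == "infected", "firebrick", "steelblue")
  graphics::plot(seq_len(nrow(tab)), pmax(tab$median, 0.5),
    log = "y", pch = 19, col = col,
    xlab = "case (ranked)", ylab = "median neutrophils per HPF", ...
  )
  graphics::abline(h = x$threshold, lty = 2)
  if (all(c("q1", "q3") %in% names(tab))) {
    graphics::segments(
      seq_len(nrow(tab)), pmax(tab$q1, 0.5),
      seq_len(nrow(tab)), pmax(tab$q3, 0.5),
      col = col
    )
  }
  invisible(x)
}

#' Bundled example cohort
#'
#' Per-case high-powered-field count summaries (patch count, median, IQR)
#' and reference diagnoses (histology, microbiology culture, and the
#' multidisciplinary-team verdict) for a 19-case periprosthetic-tissue
#' evaluation series, as used in the worked examples.
#'
#' @return Data frame with one row per case.
#' @export
example_cohort <- function() {
  read.csv(system.file("extdata", "pji_cohort.csv", package = "neutrocount"))
}

#' Read reference diagnoses from CSV
#'
#' @param path CSV with columns `case_id` and any of `histology`,
#'   `microbiology`, `mdt`.
#' @return Data frame of reference labels.
#' @export
read_references <- function(path) {
  if (!file.exists(path)) stop_invalid("reference file not found: %s", path)
  d <- read.csv(path)
  if (!"case_id" %in% names(d)) stop_invalid("reference file needs a case_id column")
  d
}
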