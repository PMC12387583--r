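# Paired comparisons with a normality gate, and SSQ summaries.
#
# Each screening condition is compared with the control on subject-level
# mean absolute deviations. Paired differences are gated by a Shapiro-Wilk
# test at alpha = 0.05: normal differences go to the paired t-test,
# non-normal ones to the Wilcoxon signed-rank test. All tests are
# two-tailed at alpha = 0.05; no multiplicity correction by default
# (matching the screening presentation), Holm available by switch.

#' Paired comparison of one condition against the control
#'
#' @param condition_values,control_values Subject-level mean absolute
#'   deviations (PD) for the test condition and for the control, paired by
#'   position (same subjects, same order), `n >= 3`.
#' @param condition Label for the test condition (metadata).
#' @param alpha Significance level, two-tailed. Default 0.05.
#' @return A one-row data.frame of class `comparison_result`: `condition,
#'   reference, test_used, normality_p, p_value, significant`.
#' @examples
#' x <- c(3.2, 4.1, 2.8, 3.9, 3.5)
#' ctrl <- c(0.6, 0.7, 0.6, 0.8, 0.7)
#' compare_to_control(x, ctrl, condition = "NFV10")
#' @export
compare_to_control <- function(condition_values, control_values,
                               condition = "condition", alpha = 0.05) {
  if (length(condition_values) != length(control_values)) {
    stop("paired vectors must have equal length")
  }
  n <- length(condition_values)
  if (n < 3L) stop("paired comparison requires n >= 3")
  if (any(!is.finite(condition_values)) || any(!is.finite(control_values))) {
    stop("paired values must be finite")
  }
  d <- condition_values - control_values

  if (all(d == 0)) {
    # No information against the null under either branch.
    return(comparison_row(condition, "wilcoxon_signed_rank", NA_real_, 1,
                          FALSE))
  }
  normality_p <- tryCatch(stats::shapiro.test(d)$p.value,
                          error = function(e) NA_real_)
  gate_normal <- is.finite(normality_p) && normality_p > alpha
  if (gate_normal) {
    p <- stats::t.test(condition_values, control_values,
                       paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(condition_values, control_values,
                         paired = TRUE)$p.value)
    test <- "wilcoxon_signed_rank"
  }
  comparison_row(condition, test, normality_p, p, p <= alpha)
}

comparison_row <- function(condition, test, normality_p, p, significant) {
  structure(
    data.frame(
      condition = condition,
      reference = "CONTROL",
      test_used = test,
      normality_p = normality_p,
      p_value = p,
      significant = significant,
      stringsAsFactors = FALSE
    ),
    class = c("comparison_result", "data.frame")
  )
}

#' Compare every non-control condition in a shot-record table to control
#'
#' Subject-level means are computed per condition; subjects lacking either
#' the condition or the control are dropped pairwise.
#'
#' @param records Shot records including a `CONTROL` condition.
#' @param alpha Significance level. Default 0.05.
#' @param adjust `"none"` (default) or `"holm"` across the condition
#'   comparisons.
#' @return A data.frame with one comparison row per non-control condition,
#'   ordered `PFV10, PFV20, NFV10, NFV20` (those present).
#' @export
compare_all_conditions <- function(records, alpha = 0.05,
                                   adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  per_subj <- subject_condition_means(records)
  if (!"CONTROL" %in% per_subj$condition) {
    stop("records contain no CONTROL condition to compare against")
  }
  ctrl <- per_subj[per_subj$condition == "CONTROL", ]
  conds <- intersect(c("PFV10", "PFV20", "NFV10", "NFV20"),
                     unique(per_subj$condition))
  rows <- lapply(conds, function(cc) {
    sub <- per_subj[per_subj$condition == cc, ]
    common <- intersect(sub$subject_id, ctrl$subject_id)
    compare_to_control(
      sub$mean_abs_deviation[match(common, sub$subject_id)],
      ctrl$mean_abs_deviation[match(common, ctrl$subject_id)],
      condition = cc, alpha = alpha
    )
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- out$p_value <= alpha
  }
  rownames(out) <- NULL
  out
}

SSQ_ITEMS <- c("general discomfort", "fatigue", "headache", "eye strain",
               "difficulty focusing", "increased salivation", "sweating",
               "nausea", "difficulty concentrating", "fullness of head",
               "blurred vision", "dizziness with eyes open",
               "dizziness with eyes closed", "vertigo",
               "stomach awareness", "burping")

#' Summarize pre/post Simulator Sickness Questionnaire responses
#'
#' Items are scored on an ordinal four-point scale (1-4) and are treated as
#' ordinal throughout: per-item means pre and post, the delta, and a paired
#' Wilcoxon signed-rank p-value (never a t-test). A subject missing one
#' phase of an item is excluded pairwise for that item with a warning.
#'
#' @param responses Data.frame with columns `subject_id, phase, item,
#'   score`; `phase` in `pre`/`post`, `score` an integer 1-4.
#' @return Per-item data.frame: `item, n, mean_pre, mean_post, delta,
#'   p_value`.
#' @export
ssq_summary <- function(responses) {
  needed <- c("subject_id", "phase", "item", "score")
  if (!all(needed %in% names(responses))) {
    stop("SSQ responses need columns: ", paste(needed, collapse = ", "))
  }
  if (!all(responses$phase %in% c("pre", "post"))) {
    stop("`phase` must be 'pre' or 'post'")
  }
  if (!all(responses$score %in% 1:4)) {
    stop("SSQ scores must be integers in 1..4")
  }
  items <- unique(responses$item)
  rows <- lapply(items, function(it) {
    sub <- responses[responses$item == it, ]
    pre <- sub[sub$phase == "pre", ]
    post <- sub[sub$phase == "post", ]
    common <- intersect(pre$subject_id, post$subject_id)
    dropped <- setdiff(unique(sub$subject_id), common)
    if (length(dropped)) {
      warning(sprintf("item '%s': subject(s) %s missing a phase; excluded",
                      it, paste(dropped, collapse = ", ")))
    }
    if (length(common) < 2L) {
      stop(sprintf("item '%s': fewer than 2 complete pre/post pairs; ",
                   it), "paired test undefined")
    }
    x_pre <- pre$score[match(common, pre$subject_id)]
    x_post <- post$score[match(common, post$subject_id)]
    d <- x_post - x_pre
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(
        stats::wilcox.test(x_post, x_pre, paired = TRUE)$p.value)
    }
    data.frame(
      item = it, n = length(common),
      mean_pre = mean(x_pre), mean_post = mean(x_post),
      delta = mean(d), p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate pre/post SSQ responses for a cohort (demo helper)
#'
#' Emulates a well-tolerated session: all pre scores are 1 except rare
#' baseline symptoms, and each item independently gains one point post
#' with a small probability. Purely a convenience for end-to-end demos;
#' real SSQ data are ingested via [read_ssq_csv()].
#'
#' @param subject_ids Character vector of subject ids.
#' @param items Item set; defaults to the standard 16-item list.
#' @param p_baseline Probability a pre score is 2 rather than 1.
#' @param p_increase Probability the post score gains one point.
#' @param seed Integer seed.
#' @return A data.frame in the SSQ response format.
#' @export
simulate_ssq <- function(subject_ids, items = SSQ_ITEMS,
                         p_baseline = 0.02, p_increase = 0.05, seed) {
  if (missing(seed) || !is.finite(seed)) stop("`seed` must be a finite integer")
  set.seed(as.integer(seed))
  grid <- expand.grid(subject_id = subject_ids, item = items,
                      stringsAsFactors = FALSE)
  pre <- 1L + (stats::runif(nrow(grid)) < p_baseline)
  post <- pmin(pre + (stats::runif(nrow(grid)) < p_increase), 4L)
  rbind(
    data.frame(grid, phase = "pre", score = as.integer(pre),
               stringsAsFactors = FALSE),
    data.frame(grid, phase = "post", score = as.integer(post),
               stringsAsFactors = FALSE)
  )[, c("subject_id", "phase", "item", "score")]
}

#' Read / write SSQ responses as CSV
#'
#' Format: `subject_id,phase,item,score`.
#'
#' @param responses SSQ response data.frame.
#' @param path File path.
#' @return `write_ssq_csv` returns `path` invisibly; `read_ssq_csv` the
#'   data.frame.
#' @export
write_ssq_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssq_csv
#' @export
read_ssq_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
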