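# Scoring: hitting deviation, horizontal fusional vergence, cohort tables.
#
# The headline statistic per condition is the mean absolute hitting
# deviation theta_HD (PD) and the total vergence amplitude
# HFV = theta_CR - theta_HD, the vergence actually performed. theta_HD is
# the MEAN ABSOLUTE deviation: absolute is the only reading under which the
# divergence conditions satisfy the formula and the control deviation is
# positive; signed per-shot values stay available for diagnostics.

#' Horizontal fusional vergence from camera rotation and hitting deviation
#'
#' `HFV = theta_CR - theta_HD`, exact subtraction with no clamping. Both
#' inputs are non-negative magnitudes in prism diopters.
#'
#' @param theta_cr Camera rotation angle (the imposed vergence demand), PD.
#' @param theta_hd Mean absolute hitting deviation, PD.
#' @return Total vergence amplitude in PD. Negative values can only arise
#'   in the degenerate control case (`theta_cr = 0` with non-zero aiming
#'   error) and are reported as computed.
#' @examples
#' hfv(10, 3.40) # 6.60
#' hfv(20, 9.95) # 10.05
#' @export
hfv <- function(theta_cr, theta_hd) {
  if (any(!is.finite(theta_cr)) || any(theta_cr < 0)) {
    stop("`theta_cr` must be finite and >= 0")
  }
  if (any(!is.finite(theta_hd)) || any(theta_hd < 0)) {
    stop("`theta_hd` must be finite and >= 0")
  }
  theta_cr - theta_hd
}

#' Summarize the shots of a single condition
#'
#' @param records Shot records all sharing one condition (for one subject
#'   or pooled; the cohort-level path aggregates per subject first, see
#'   [summarize_cohort()]).
#' @param theta_cr Camera rotation of the condition, PD. Defaults to the
#'   built-in value for the records' condition label.
#' @return A one-row data.frame: `condition, theta_cr, mean_abs_deviation,
#'   sd_deviation, total_vergence, n_shots`.
#' @export
summarize_condition <- function(records, theta_cr = NULL) {
  if (nrow(records) == 0L) stop("no shot records to summarize")
  cond <- unique(records$condition)
  if (length(cond) != 1L) {
    stop("records span multiple conditions: ", paste(cond, collapse = ", "))
  }
  if (is.null(theta_cr)) theta_cr <- condition_set(cond)$theta_cr
  dev <- abs(records$deviation_pd)
  m <- mean(dev)
  data.frame(
    condition = cond,
    theta_cr = theta_cr,
    mean_abs_deviation = m,
    sd_deviation = if (length(dev) > 1L) stats::sd(dev) else 0,
    total_vergence = hfv(theta_cr, m),
    n_shots = length(dev),
    stringsAsFactors = FALSE
  )
}

# Per-(subject, condition) mean absolute deviation -- the subject-level
# statistic every cohort summary and comparison is built on.
subject_condition_means <- function(records) {
  agg <- stats::aggregate(
    abs(records$deviation_pd),
    by = list(subject_id = records$subject_id,
              condition = records$condition),
    FUN = mean
  )
  names(agg)[3] <- "mean_abs_deviation"
  n <- stats::aggregate(
    records$deviation_pd,
    by = list(subject_id = records$subject_id,
              condition = records$condition),
    FUN = length
  )
  agg$n_shots <- n$x
  agg
}

#' Cohort-level condition summaries (two-stage aggregation)
#'
#' Shots are first averaged within subject, then the cohort mean and SD are
#' taken across subjects -- each subject contributes equally regardless of
#' shot count. Rows are ordered `CONTROL, PFV10, PFV20, NFV10, NFV20`.
#'
#' A subject missing a condition is excluded from that condition with a
#' warning. With a single subject the across-subject SD is undefined and is
#' reported as 0 with `sd_flag = "single-subject"`. The control row's total
#' vergence is the degenerate `0 - mean deviation` (negative) and carries
#' `note = "degenerate-control"`.
#'
#' @param records Shot records spanning one or more subjects.
#' @return A data.frame with one row per condition present: `condition,
#'   theta_cr, mean_abs_deviation, sd_deviation, total_vergence,
#'   n_subjects, n_shots, sd_flag, note`.
#' @examples
#' cohort <- sample_cohort(cohort_spec(n_subjects = 4), seed = 11)
#' shots <- run_cohort(cohort, protocol_spec(shots_per_condition = 10), seed = 11)
#' summarize_cohort(shots)
#' @export
summarize_cohort <- function(records) {
  validate_shots(records)
  per_subj <- subject_condition_means(records)
  subjects <- unique(records$subject_id)
  conditions <- intersect(c("CONTROL", "PFV10", "PFV20", "NFV10", "NFV20"),
                          unique(per_subj$condition))
  rows <- lapply(conditions, function(cc) {
    sub <- per_subj[per_subj$condition == cc, ]
    absent <- setdiff(subjects, sub$subject_id)
    if (length(absent)) {
      warning(sprintf("condition %s missing for subject(s) %s; excluded",
                      cc, paste(absent, collapse = ", ")))
    }
    theta <- condition_set(cc)$theta_cr
    m <- mean(sub$mean_abs_deviation)
    single <- nrow(sub) == 1L
    data.frame(
      condition = cc,
      theta_cr = theta,
      mean_abs_deviation = m,
      sd_deviation = if (single) 0 else stats::sd(sub$mean_abs_deviation),
      total_vergence = hfv(theta, m),
      n_subjects = nrow(sub),
      n_shots = sum(sub$n_shots),
      sd_flag = if (single) "single-subject" else "",
      note = if (cc == "CONTROL") "degenerate-control" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort summary as a report JSON
#'
#' One object per condition with fields `condition, theta_cr_pd,
#' mean_abs_deviation_pd, sd_pd, total_vergence_pd, n_subjects, n_shots`,
#' plus optional provenance (`config` echo).
#'
#' @param summary Output of [summarize_cohort()].
#' @param path Output file.
#' @param config Optional configuration list echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(summary, path, config = NULL) {
  payload <- list(
    conditions = lapply(seq_len(nrow(summary)), function(i) {
      list(
        condition = summary$condition[i],
        theta_cr_pd = summary$theta_cr[i],
        mean_abs_deviation_pd = summary$mean_abs_deviation[i],
        sd_pd = summary$sd_deviation[i],
        total_vergence_pd = summary$total_vergence[i],
        n_subjects = summary$n_subjects[i],
        n_shots = summary$n_shots[i],
        note = summary$note[i]
      )
    })
  )
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render the summary in the published table layout
#'
#' CSV with columns `target_vergence, total_vergence_pd, average_deviation_pd`
#' (each "mean +/- SD") in the row order control, PFV10, PFV20, NFV10,
#' NFV20.
#'
#' @param summary Output of [summarize_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(summary, path) {
  fmt <- function(m, s) sprintf("%.2f +/- %.2f", m, s)
  labels <- c(CONTROL = "Control, 0 PD", PFV10 = "PFV 10 PD",
              PFV20 = "PFV 20 PD", NFV10 = "NFV 10 PD", NFV20 = "NFV 20 PD")
  df <- data.frame(
    target_vergence = labels[summary$condition],
    total_vergence_pd = fmt(summary$total_vergence, summary$sd_deviation),
    average_deviation_pd = fmt(summary$mean_abs_deviation,
                               summary$sd_deviation),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bar-plot helper for per-condition mean deviations
#'
#' Minimal base-graphics rendering of the condition summary (mean absolute
#' deviation with SD whiskers).
#'
#' @param summary Output of [summarize_cohort()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_deviation <- function(summary, ...) {
  mids <- graphics::barplot(summary$mean_abs_deviation,
                            names.arg = summary$condition,
                            ylab = "mean |hitting deviation| (PD)",
                            ylim = c(0, max(summary$mean_abs_deviation +
                                              summary$sd_deviation) * 1.1),
                            ...)
  graphics::arrows(mids, summary$mean_abs_deviation,
                   mids, summary$mean_abs_deviation + summary$sd_deviation,
                   angle = 90, length = 0.05)
  invisible(mids)
}
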