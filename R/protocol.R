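# Five-condition screening session engine.
#
# Conditions: CONTROL (no rotation), NFV10/NFV20 (inward image rotation of
# 10/20 PD, requiring divergence) and PFV10/PFV20 (outward rotation,
# requiring convergence). A session runs CONTROL first, then the two NFV
# conditions in random order, then the two PFV conditions in random order:
# divergence is always exercised before convergence to avoid vergence
# after-effects, while the within-block order stays randomized.

CONDITION_LEVELS <- c("CONTROL", "NFV10", "NFV20", "PFV10", "PFV20")

#' The built-in screening conditions
#'
#' @param labels Subset of `CONTROL, NFV10, NFV20, PFV10, PFV20`; defaults
#'   to all five.
#' @return A data.frame with columns `label`, `theta_cr` (camera rotation
#'   in PD), `image_rotation` (`none`/`inward`/`outward`) and
#'   `required_response` (`none`/`divergence`/`convergence`).
#' @export
condition_set <- function(labels = CONDITION_LEVELS) {
  tbl <- data.frame(
    label = CONDITION_LEVELS,
    theta_cr = c(0, 10, 20, 10, 20),
    image_rotation = c("none", "inward", "inward", "outward", "outward"),
    required_response = c("none", "divergence", "divergence",
                          "convergence", "convergence"),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(labels, tbl$label)
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(bad, collapse = ", "))
  tbl[match(labels, tbl$label), , drop = FALSE]
}

#' Randomized block order of the screening conditions
#'
#' CONTROL always comes first; the divergence (NFV) block precedes the
#' convergence (PFV) block; order within each block is randomized from the
#' session RNG. When `labels` is a subset, the same block rules apply to
#' the conditions present.
#'
#' @param labels Conditions to order (default all five).
#' @return Character vector of condition labels in presentation order.
#' @export
condition_order <- function(labels = CONDITION_LEVELS) {
  shuffle <- function(x) if (length(x) > 1L) sample(x) else x
  c(
    intersect("CONTROL", labels),
    shuffle(intersect(c("NFV10", "NFV20"), labels)),
    shuffle(intersect(c("PFV10", "PFV20"), labels))
  )
}

#' Draw a balloon center position for one trial
#'
#' The offset magnitude is chosen uniformly from the world's lateral
#' offsets; for non-zero magnitudes a side (left/right) is then chosen by
#' fair coin. Height is eye height; depth is the viewing distance.
#'
#' @param world A [world_config()].
#' @param n Number of positions to draw.
#' @return For `n = 1` a [world_point()]; otherwise a matrix with columns
#'   `x`, `y`, `z`.
#' @export
sample_balloon_center <- function(world, n = 1L) {
  mags <- world$lateral_offsets_m[
    sample.int(length(world$lateral_offsets_m), n, replace = TRUE)]
  side <- ifelse(stats::runif(n) < 0.5, -1, 1)
  x <- ifelse(mags == 0, 0, side * mags)
  if (n == 1L) {
    world_point(x, world$eye_height_m, world$viewing_distance_m)
  } else {
    cbind(x = x, y = rep(world$eye_height_m, n),
          z = rep(world$viewing_distance_m, n))
  }
}

#' Protocol specification
#'
#' @param shots_per_condition Shots fired in each condition, `>= 1`.
#'   Default 40.
#' @param conditions Condition labels to run (default all five).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(shots_per_condition = 40L,
                          conditions = CONDITION_LEVELS) {
  if (!is.finite(shots_per_condition) || shots_per_condition < 1) {
    stop("`shots_per_condition` must be >= 1")
  }
  condition_set(conditions)  # validates labels
  structure(
    list(
      shots_per_condition = as.integer(shots_per_condition),
      conditions = conditions
    ),
    class = "protocol_spec"
  )
}

#' Run one subject through the screening session
#'
#' Emits one shot record per trial. The control eye is reassigned by fair
#' coin after every shot; the balloon is re-positioned per shot; the
#' recorded `deviation_pd` is recomputed from the stored coordinates so the
#' record is internally consistent.
#'
#' @param subject A [synthetic_subject()].
#' @param protocol A [protocol_spec()].
#' @param world A [world_config()].
#' @param seed Integer seed for the session substream.
#' @return A data.frame of shot records with columns `subject_id,
#'   condition, shot_index, control_eye, balloon_x_m, balloon_y_m,
#'   balloon_z_m, hit_x_m, hit_y_m, hit_z_m, deviation_pd`.
#' @export
run_session <- function(subject, protocol = protocol_spec(),
                        world = world_config(), seed) {
  if (!inherits(subject, "synthetic_subject")) {
    stop("`subject` must be a synthetic_subject")
  }
  if (!inherits(protocol, "protocol_spec")) {
    stop("`protocol` must be a protocol_spec")
  }
  if (!inherits(world, "world_config")) stop("`world` must be a world_config")
  if (missing(seed) || !is.finite(seed)) stop("`seed` must be a finite integer")
  set.seed(as.integer(seed))

  order <- condition_order(protocol$conditions)
  cond <- condition_set(order)
  nshots <- protocol$shots_per_condition
  z <- world$viewing_distance_m

  blocks <- lapply(seq_len(nrow(cond)), function(i) {
    direction <- cond$required_response[i]
    centers <- sample_balloon_center(world, n = nshots)
    centers <- matrix(centers, ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    eyes <- ifelse(stats::runif(nshots) < 0.5, "left", "right")
    resid <- residual_demand(subject, cond$theta_cr[i], direction)
    err_pd <- resid + draw_baseline_error(subject, nshots)
    sgn <- hit_sign(eyes, direction)
    hit_x <- centers[, "x"] + pd_to_lateral_offset(sgn * err_pd, z)
    data.frame(
      subject_id = subject$subject_id,
      condition = cond$label[i],
      shot_index = seq_len(nshots),
      control_eye = eyes,
      balloon_x_m = centers[, "x"],
      balloon_y_m = centers[, "y"],
      balloon_z_m = centers[, "z"],
      hit_x_m = hit_x,
      hit_y_m = centers[, "y"],
      hit_z_m = centers[, "z"],
      deviation_pd = deviation_pd_vec(hit_x, centers[, "x"], z),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}

# Deterministic per-subject substream: adding subjects to a cohort never
# perturbs the streams of earlier subjects.
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 104729 * index) %% 2147483647)
}

#' Run a whole cohort through the protocol
#'
#' Subjects are processed in `subject_id` order, each on its own RNG
#' substream derived from `seed`.
#'
#' @param cohort Non-empty list of [synthetic_subject()]s with unique ids.
#' @inheritParams run_session
#' @return Row-bound shot records for all subjects.
#' @examples
#' cohort <- sample_cohort(cohort_spec(n_subjects = 2), seed = 7)
#' shots <- run_cohort(cohort, protocol_spec(shots_per_condition = 5), seed = 7)
#' nrow(shots) # 2 * 5 * 5
#' @export
run_cohort <- function(cohort, protocol = protocol_spec(),
                       world = world_config(), seed) {
  if (length(cohort) == 0L) stop("`cohort` must contain at least one subject")
  ids <- vapply(cohort, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject_id in cohort")
  cohort <- cohort[order(ids)]
  out <- lapply(seq_along(cohort), function(i) {
    run_session(cohort[[i]], protocol, world,
                seed = subject_seed(seed, i))
  })
  do.call(rbind, out)
}

SHOT_COLUMNS <- c("subject_id", "condition", "shot_index", "control_eye",
                  "balloon_x_m", "balloon_y_m", "balloon_z_m",
                  "hit_x_m", "hit_y_m", "hit_z_m", "deviation_pd")

#' Write / read shot records as CSV
#'
#' The interchange format between the simulate and score stages and the
#' ingestion format for externally logged sessions: UTF-8, '.' decimal
#' separator, header `subject_id,condition,shot_index,control_eye,
#' balloon_x_m,balloon_y_m,balloon_z_m,hit_x_m,hit_y_m,hit_z_m,deviation_pd`.
#' Numbers are written with full precision (15 significant digits) so a
#' repeated seeded run produces a byte-identical file.
#'
#' @param records Shot-record data.frame.
#' @param path File path.
#' @return `write_shots_csv` returns `path` invisibly; `read_shots_csv`
#'   returns a validated data.frame.
#' @export
write_shots_csv <- function(records, path) {
  stopifnot(all(SHOT_COLUMNS %in% names(records)))
  df <- records[, SHOT_COLUMNS]
  num <- vapply(df, is.numeric, TRUE) & names(df) != "shot_index"
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shots_csv
#' @export
read_shots_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SHOT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("shot CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  validate_shots(df)
  df
}

# Internal-consistency check shared by readers and the scorer.
validate_shots <- function(records, tol = 1e-6) {
  if (nrow(records) == 0L) stop("no shot records")
  if (!all(records$condition %in% CONDITION_LEVELS)) {
    stop("unknown condition labels in shot records")
  }
  dev <- deviation_pd_vec(records$hit_x_m, records$balloon_x_m,
                          records$balloon_z_m)
  if (any(abs(dev - records$deviation_pd) > tol)) {
    stop("deviation_pd is inconsistent with the recorded coordinates")
  }
  invisible(records)
}
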