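test_that("condition metadata encodes rotation and required response", {
  tbl <- condition_set()
  expect_equal(tbl$label, c("CONTROL", "NFV10", "NFV20", "PFV10", "PFV20"))
  expect_equal(tbl$theta_cr, c(0, 10, 20, 10, 20))
  # inward rotation <=> divergence, outward <=> convergence, control <=> none
  expect_equal(tbl$required_response[tbl$image_rotation == "inward"],
               rep("divergence", 2))
  expect_equal(tbl$required_response[tbl$image_rotation == "outward"],
               rep("convergence", 2))
  expect_equal(tbl$theta_cr[tbl$image_rotation == "none"], 0)
  expect_error(condition_set("NFV15"), "unknown condition")
})

test_that("condition order: control first, divergence block before convergence", {
  seen <- character(0)
  for (seed in 1:50) {
    set.seed(seed)
    ord <- condition_order()
    expect_setequal(ord, condition_set()$label)
    expect_equal(ord[1], "CONTROL")
    expect_lt(max(match(c("NFV10", "NFV20"), ord)),
              min(match(c("PFV10", "PFV20"), ord)))
    seen <- c(seen, paste(ord, collapse = ","))
  }
  # randomization actually happens within blocks
  expect_gt(length(unique(seen)), 1)
})

test_that("balloon centers sample offset magnitudes uniformly", {
  w <- world_config()
  set.seed(21)
  pts <- sample_balloon_center(w, n = 9999)
  expect_true(all(pts[, "z"] == 6))
  mag <- abs(pts[, "x"])
  expect_setequal(unique(mag), c(0, 0.5, 1))
  # 4-sigma binomial band around 1/3
  tol <- 4 * sqrt((1 / 3) * (2 / 3) / 9999)
  for (m in c(0, 0.5, 1)) {
    expect_lt(abs(mean(mag == m) - 1 / 3), tol)
  }
  # sides balanced among non-zero offsets
  nz <- pts[mag > 0, "x"]
  expect_lt(abs(mean(nz > 0) - 0.5), 4 * sqrt(0.25 / length(nz)))
  # degenerate world
  w0 <- world_config(lateral_offsets_m = 0)
  set.seed(1)
  expect_true(all(sample_balloon_center(w0, n = 100)[, "x"] == 0))
})

test_that("run_session emits consistent, reproducible records", {
  s <- synthetic_subject("S1", 18, 10)
  shots <- run_session(s, protocol_spec(), world_config(), seed = 17)
  expect_equal(nrow(shots), 200)
  expect_equal(sort(unique(shots$condition)), sort(condition_set()$label))
  expect_true(all(table(shots$condition) == 40))
  # internal consistency of every record
  expect_equal(shots$deviation_pd,
               100 * (shots$hit_x_m - shots$balloon_x_m) / shots$balloon_z_m,
               tolerance = 1e-9)
  # shot_index unique within (subject, condition)
  expect_false(any(duplicated(shots[c("subject_id", "condition",
                                      "shot_index")])))
  # single condition, single shot
  one <- run_session(s, protocol_spec(1, "CONTROL"), world_config(),
                     seed = 17)
  expect_equal(nrow(one), 1)
  # determinism
  expect_identical(run_session(s, seed = 17), run_session(s, seed = 17))
})

test_that("run_cohort conserves record counts and is id-stable", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 4), seed = 5)
  prot <- protocol_spec(shots_per_condition = 6)
  shots <- run_cohort(cohort, prot, seed = 5)
  expect_equal(nrow(shots), 4 * 5 * 6)
  expect_identical(shots, run_cohort(cohort, prot, seed = 5))
  # reordering the cohort list does not change the output (id order rules)
  expect_identical(run_cohort(rev(cohort), prot, seed = 5), shots)
  # growing the cohort leaves earlier subjects' records untouched
  bigger <- c(cohort, list(synthetic_subject("S999", 18, 10)))
  shots_big <- run_cohort(bigger, prot, seed = 5)
  head_rows <- shots_big[shots_big$subject_id != "S999", ]
  rownames(head_rows) <- NULL
  expect_equal(head_rows, shots)
  expect_error(run_cohort(list(), prot, seed = 5), "at least one")
  expect_error(run_cohort(c(cohort, cohort[1]), prot, seed = 5),
               "duplicate")
})

test_that("control eye assignment is a fair per-shot coin", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 10), seed = 9)
  shots <- run_cohort(cohort, protocol_spec(), seed = 9)
  n <- nrow(shots)
  expect_lt(abs(mean(shots$control_eye == "left") - 0.5),
            4 * sqrt(0.25 / n))
})

test_that("scoring is invariant to the balloon offset magnitude", {
  # |deviation| must not depend on where the balloon happened to be
  cohort <- sample_cohort(cohort_spec(n_subjects = 30), seed = 13)
  shots <- run_cohort(cohort, protocol_spec(conditions = "CONTROL"),
                      seed = 13)
  fit <- stats::lm(abs(shots$deviation_pd) ~ abs(shots$balloon_x_m))
  expect_lt(abs(stats::coef(fit)[2]), 0.06)
})

test_that("shot CSV round-trips byte-identically under a repeated seed", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 2), seed = 31)
  prot <- protocol_spec(shots_per_condition = 10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_shots_csv(run_cohort(cohort, prot, seed = 31), p1)
  write_shots_csv(run_cohort(cohort, prot, seed = 31), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_shots_csv(p1)
  orig <- run_cohort(cohort, prot, seed = 31)
  expect_equal(back$deviation_pd, orig$deviation_pd, tolerance = 1e-9)
  expect_identical(back$condition, orig$condition)
})

test_that("shot readers reject malformed or inconsistent records", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 1), seed = 1)
  shots <- run_cohort(cohort, protocol_spec(shots_per_condition = 3),
                      seed = 1)
  bad <- shots
  bad$deviation_pd[1] <- bad$deviation_pd[1] + 1
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_shots_csv(p), "inconsistent")
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shots[, 1:4], p2, row.names = FALSE)
  expect_error(read_shots_csv(p2), "missing columns")
})
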