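test_that("achieved vergence is a hard clamp at the directional amplitude", {
  s <- synthetic_subject("A", pfv_amplitude = 18, nfv_amplitude = 8)
  expect_equal(achieved_vergence(s, 10, "convergence"), 10)
  expect_equal(achieved_vergence(s, 20, "divergence"), 8)
  expect_equal(achieved_vergence(s, 0, "divergence"), 0)
  expect_equal(achieved_vergence(s, 0, "none"), 0)
  expect_error(achieved_vergence(s, -1, "convergence"), ">= 0")
})

test_that("residual demand is demand minus achieved, zero iff fusible", {
  s18 <- synthetic_subject("A", pfv_amplitude = 18, nfv_amplitude = 10.05)
  expect_equal(residual_demand(s18, 20, "convergence"), 2)
  expect_equal(residual_demand(s18, 20, "divergence"), 9.95)
  s8 <- synthetic_subject("B", pfv_amplitude = 8, nfv_amplitude = 8)
  expect_equal(residual_demand(s8, 8, "divergence"), 0)
  expect_true(residual_demand(s8, 8 + 1e-9, "divergence") > 0)
})

test_that("residual demand is monotone in demand and amplitude (noiseless)", {
  demands <- seq(0, 30, by = 2.5)
  amps <- c(0, 4, 9, 14, 25)
  for (a in amps) {
    s <- noiseless_subject(nfv = a)
    r <- vapply(demands, function(d) residual_demand(s, d, "divergence"), 0)
    expect_true(all(diff(r) >= 0))
  }
  for (d in demands) {
    r <- vapply(amps, function(a) {
      residual_demand(noiseless_subject(nfv = a), d, "divergence")
    }, 0)
    expect_true(all(diff(r) <= 0))
  }
})

test_that("folded-normal baseline error matches the calibrated moments", {
  s <- synthetic_subject("A", 18, 10,
                         baseline_bias_mean = 0.65, motor_noise_sd = 0.25)
  # analytic moments of |N(bias_mu, bias_sigma)| must hit the targets
  mu <- s$bias_mu; sg <- s$bias_sigma
  m <- sg * sqrt(2 / pi) * exp(-mu^2 / (2 * sg^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sg))
  expect_equal(m, 0.65, tolerance = 1e-9)
  expect_equal(sqrt(mu^2 + sg^2 - m^2), 0.25, tolerance = 1e-9)
  # and empirically
  set.seed(1)
  e <- vergescreen:::draw_baseline_error(s, 2e5)
  expect_true(all(e >= 0))
  expect_equal(mean(e), 0.65, tolerance = 0.01)
  expect_equal(stats::sd(e), 0.25, tolerance = 0.02)
})

test_that("infeasible bias/noise calibrations are rejected", {
  expect_error(synthetic_subject("A", 18, 10, baseline_bias_mean = 0,
                                 motor_noise_sd = 0.25), "infeasible")
  expect_error(synthetic_subject("A", 18, 10, baseline_bias_mean = 0.1,
                                 motor_noise_sd = 0.2), "coefficient")
  # degenerate but valid: constant error, and no error at all
  s0 <- synthetic_subject("A", 18, 10, baseline_bias_mean = 0.5,
                          motor_noise_sd = 0)
  expect_equal(vergescreen:::draw_baseline_error(s0, 3), rep(0.5, 3))
  expect_equal(vergescreen:::draw_baseline_error(noiseless_subject(), 3),
               rep(0, 3))
})

test_that("simulate_hit realizes the residual in the balloon plane", {
  ctr <- default_balloon(x = 0.5)
  # perfect fusion: hit at the center exactly
  set.seed(5)
  hit <- simulate_hit(noiseless_subject(nfv = 12), 10, "divergence", ctr)
  expect_equal(unclass(hit), unclass(ctr))
  # clamped: residual 10 PD -> 0.6 m at 6 m
  set.seed(5)
  hit <- simulate_hit(noiseless_subject(nfv = 10), 20, "divergence", ctr)
  expect_equal(abs(hit[["x"]] - ctr[["x"]]), 0.6, tolerance = 1e-12)
  expect_equal(hit[["z"]], ctr[["z"]])
  # determinism under a fixed seed
  s <- synthetic_subject("A", 18, 10)
  set.seed(99); h1 <- simulate_hit(s, 20, "divergence", ctr, n = 5)
  set.seed(99); h2 <- simulate_hit(s, 20, "divergence", ctr, n = 5)
  expect_identical(h1, h2)
})

test_that("zero-noise hit + deviation equals residual over the oracle grid", {
  # brute-force oracle: demand - min(demand, amplitude)
  for (amp in c(0, 5, 8, 10, 16, 25)) {
    for (demand in c(0, 10, 20)) {
      for (dir in c("convergence", "divergence")) {
        s <- noiseless_subject(pfv = amp, nfv = amp)
        hit <- simulate_hit(s, demand, dir, default_balloon())
        dev <- abs(hitting_deviation_pd(hit, default_balloon()))
        expect_equal(dev, demand - min(demand, amp), tolerance = 1e-9)
      }
    }
  }
})

test_that("fusion plateau: sub-amplitude demand is distributed like control", {
  # identical RNG stream => identical error draws; only the residual differs
  s <- synthetic_subject("A", 18, 10)
  set.seed(123)
  h_ctrl <- simulate_hit(s, 0, "none", default_balloon(), n = 500)
  set.seed(123)
  h_pfv10 <- simulate_hit(s, 10, "convergence", default_balloon(), n = 500)
  d_ctrl <- abs(vergescreen:::deviation_pd_vec(h_ctrl[, "x"], 0, 6))
  d_pfv <- abs(vergescreen:::deviation_pd_vec(h_pfv10[, "x"], 0, 6))
  expect_equal(d_ctrl, d_pfv, tolerance = 1e-12)
})

test_that("sample_cohort draws reproducible truncated-normal amplitudes", {
  spec <- cohort_spec(n_subjects = 19, pfv_sd = 0, nfv_sd = 0)
  cohort <- sample_cohort(spec, seed = 3)
  expect_length(cohort, 19)
  expect_true(all(vapply(cohort, `[[`, 0, "pfv_amplitude") == 18))
  expect_true(all(vapply(cohort, `[[`, 0, "nfv_amplitude") == 10))

  big <- sample_cohort(cohort_spec(n_subjects = 1000, pfv_mean = 20,
                                   pfv_sd = 3), seed = 4)
  pfv <- vapply(big, `[[`, 0, "pfv_amplitude")
  expect_true(all(pfv > 0))
  expect_lt(abs(mean(pfv) - 20), 3 * 3 / sqrt(1000))

  c1 <- sample_cohort(cohort_spec(), seed = 8)
  c2 <- sample_cohort(cohort_spec(), seed = 8)
  expect_identical(c1, c2)
})

test_that("cohort CSV round-trips", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 5), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(vapply(back, `[[`, "", "subject_id"),
               vapply(cohort, `[[`, "", "subject_id"))
  expect_equal(vapply(back, `[[`, 0, "nfv_amplitude"),
               vapply(cohort, `[[`, 0, "nfv_amplitude"), tolerance = 1e-12)
  expect_error(read_cohort_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "missing columns")
})
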