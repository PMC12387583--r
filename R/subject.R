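# Parametric synthetic observer.
#
# Each subject carries a convergence (PFV) and a divergence (NFV) amplitude
# in prism diopters. The vergence response to a demand is a hard clamp at
# the amplitude: demands at or below the amplitude are fully met (fusion),
# anything beyond leaves a residual demand that reappears as hitting
# deviation. Baseline aiming error -- present even with zero demand -- is a
# folded-normal draw added to the residual on every shot, calibrated so its
# folded mean equals `baseline_bias_mean` and its folded SD equals
# `motor_noise_sd`.

#' Construct a synthetic observer
#'
#' @param subject_id Character token identifying the subject.
#' @param pfv_amplitude Maximum sustainable convergence, prism diopters
#'   (PD), `>= 0`. Demands up to this amplitude are fused under outward
#'   image rotation.
#' @param nfv_amplitude Maximum sustainable divergence, PD, `>= 0`.
#' @param baseline_bias_mean Mean absolute aiming error with zero vergence
#'   demand, PD. Default 0.65.
#' @param motor_noise_sd Per-shot SD of the absolute aiming error, PD.
#'   Default 0.25.
#' @param wears_glasses Metadata flag, not used by the model.
#' @param response `"clamp"` (default) for the all-or-nothing amplitude
#'   limit, or `"soft"` for a smooth-saturation variant
#'   (`amplitude * tanh(demand / amplitude)`) kept as an exploratory hook.
#'
#' @return An object of class `synthetic_subject`. The folded-normal
#'   location/scale implied by the bias/noise calibration are precomputed
#'   and stored as `bias_mu` / `bias_sigma`.
#' @examples
#' s <- synthetic_subject("S01", pfv_amplitude = 18, nfv_amplitude = 10)
#' achieved_vergence(s, demand = 20, direction = "divergence")
#' @export
synthetic_subject <- function(subject_id,
                              pfv_amplitude,
                              nfv_amplitude,
                              baseline_bias_mean = 0.65,
                              motor_noise_sd = 0.25,
                              wears_glasses = FALSE,
                              response = c("clamp", "soft")) {
  response <- match.arg(response)
  vals <- c(pfv_amplitude, nfv_amplitude, baseline_bias_mean, motor_noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("amplitudes, baseline bias and motor noise must be finite and >= 0")
  }
  fp <- folded_normal_params(baseline_bias_mean, motor_noise_sd)
  structure(
    list(
      subject_id = as.character(subject_id),
      pfv_amplitude = as.numeric(pfv_amplitude),
      nfv_amplitude = as.numeric(nfv_amplitude),
      baseline_bias_mean = as.numeric(baseline_bias_mean),
      motor_noise_sd = as.numeric(motor_noise_sd),
      wears_glasses = isTRUE(wears_glasses),
      response = response,
      bias_mu = fp[["mu"]],
      bias_sigma = fp[["sigma"]]
    ),
    class = "synthetic_subject"
  )
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject %s> PFV %.2f PD, NFV %.2f PD, bias %.2f +/- %.2f PD\n",
    x$subject_id, x$pfv_amplitude, x$nfv_amplitude,
    x$baseline_bias_mean, x$motor_noise_sd
  ))
  invisible(x)
}

# Solve for the location (mu) and scale (sigma) of the underlying normal so
# that |N(mu, sigma)| has the requested mean m and SD s (moment matching).
# Feasible iff s/m < sqrt(pi/2 - 1) (the half-normal CV, ~0.7555); above
# that no folded normal attains the requested spread.
folded_normal_params <- function(m, s) {
  if (m == 0 && s == 0) return(c(mu = 0, sigma = 0))
  if (m == 0) stop("baseline bias mean 0 with positive noise is infeasible ",
                   "for the folded-normal error model")
  if (s == 0) return(c(mu = m, sigma = 0))
  cv_max <- sqrt(pi / 2 - 1)
  cv <- s / m
  if (cv >= cv_max) {
    stop(sprintf(
      "motor_noise_sd / baseline_bias_mean = %.3f exceeds the folded-normal
       maximum coefficient of variation %.4f", cv, cv_max))
  }
  # theta = mu / sigma; folded mean = sigma * g(theta), E[X^2] = sigma^2 (1 + theta^2)
  g <- function(theta) {
    sqrt(2 / pi) * exp(-theta^2 / 2) + theta * (1 - 2 * stats::pnorm(-theta))
  }
  cv2 <- function(theta) (1 + theta^2) / g(theta)^2 - 1
  theta <- stats::uniroot(function(t) cv2(t) - cv^2,
                          lower = 0, upper = 60, tol = 1e-12)$root
  sigma <- m / g(theta)
  c(mu = theta * sigma, sigma = sigma)
}

# One folded-normal draw per shot: the non-negative baseline aiming error.
draw_baseline_error <- function(subject, n) {
  if (subject$bias_sigma == 0) {
    rep(subject$bias_mu, n)
  } else {
    abs(stats::rnorm(n, subject$bias_mu, subject$bias_sigma))
  }
}

amplitude_for <- function(subject, direction) {
  switch(direction,
    convergence = subject$pfv_amplitude,
    divergence = subject$nfv_amplitude,
    none = Inf,
    stop("unknown vergence direction: ", direction)
  )
}

#' Vergence actually achieved against a demand
#'
#' Under the clamp response the subject meets the demand fully up to the
#' directional amplitude and saturates beyond it; the result is
#' deterministic given the subject.
#'
#' @param subject A [synthetic_subject()].
#' @param demand Vergence demand in PD, `>= 0`.
#' @param direction `"convergence"` (PFV), `"divergence"` (NFV) or
#'   `"none"` (control; demand must be 0).
#' @return Achieved vergence in PD, in `[0, demand]`.
#' @export
achieved_vergence <- function(subject, demand,
                              direction = c("convergence", "divergence",
                                            "none")) {
  direction <- match.arg(direction)
  if (any(!is.finite(demand)) || any(demand < 0)) {
    stop("`demand` must be finite and >= 0")
  }
  amp <- amplitude_for(subject, direction)
  if (subject$response == "soft" && is.finite(amp) && amp > 0) {
    pmin(demand, amp * tanh(demand / amp))
  } else {
    pmin(demand, amp)
  }
}

#' Residual (unmet) vergence demand
#'
#' `demand - achieved_vergence(...)`; zero exactly when the demand is within
#' the subject's amplitude. Under the clamp model this residual is what
#' reappears as hitting deviation when fusion fails.
#'
#' @inheritParams achieved_vergence
#' @return Residual demand in PD, `>= 0`.
#' @export
residual_demand <- function(subject, demand,
                            direction = c("convergence", "divergence",
                                          "none")) {
  direction <- match.arg(direction)
  demand - achieved_vergence(subject, demand, direction)
}

#' Simulate aimed hit point(s) for one subject under a vergence demand
#'
#' The aiming error magnitude is `residual + e` where `e` is the subject's
#' folded-normal baseline error, converted back to meters in the balloon
#' plane. The displacement direction follows the control eye (image
#' displacement side); scoring is sign-agnostic so this only matters for
#' diagnostics.
#'
#' Randomness comes from the R session RNG: seed it (`set.seed()`) for
#' reproducibility.
#'
#' @inheritParams achieved_vergence
#' @param balloon_center A [world_point()] in the balloon plane.
#' @param control_eye `"left"` or `"right"`; which eye saw the rotated
#'   image (vector of length `n` or recycled).
#' @param n Number of shots to draw.
#' @return For `n = 1` a [world_point()]; otherwise a matrix with columns
#'   `x`, `y`, `z` (one row per shot).
#' @export
simulate_hit <- function(subject, demand,
                         direction = c("convergence", "divergence", "none"),
                         balloon_center,
                         control_eye = "right",
                         n = 1L) {
  direction <- match.arg(direction)
  if (balloon_center[["z"]] <= 0) stop("balloon must be at positive depth")
  resid <- residual_demand(subject, demand, direction)
  err_pd <- resid + draw_baseline_error(subject, n)
  sgn <- hit_sign(rep_len(control_eye, n), direction)
  dx <- pd_to_lateral_offset(sgn * err_pd, balloon_center[["z"]])
  if (n == 1L) {
    world_point(balloon_center[["x"]] + dx, balloon_center[["y"]],
                balloon_center[["z"]])
  } else {
    cbind(x = balloon_center[["x"]] + dx,
          y = rep(balloon_center[["y"]], n),
          z = rep(balloon_center[["z"]], n))
  }
}

# Sign of the horizontal displacement of the aim point. The rotated
# (control-eye) image displaces toward the rotation side: inward rotation
# of the right eye pushes its image leftward, outward rightward; mirrored
# for the left eye. Control shots inherit the same convention so the sign
# is still balanced by the per-shot eye reassignment.
hit_sign <- function(control_eye, direction) {
  eye <- ifelse(control_eye == "right", 1, -1)
  dir <- if (direction == "divergence") -1 else 1
  eye * dir
}

#' Specification of a synthetic cohort
#'
#' Amplitudes are drawn per subject from normal distributions truncated at
#' zero; bias and noise are shared across the cohort (the screening
#' population is homogeneous young orthotropic adults).
#'
#' @param n_subjects Number of subjects, `>= 1`. Default 19.
#' @param pfv_mean,pfv_sd Convergence-amplitude distribution, PD.
#'   Defaults 18 and 3 (within reported distance PFV break ranges).
#' @param nfv_mean,nfv_sd Divergence-amplitude distribution, PD.
#'   Defaults 10 and 2 (within reported distance NFV break ranges).
#' @param baseline_bias_mean,motor_noise_sd Shared aiming-error calibration,
#'   PD. Defaults 0.65 and 0.25 (control-condition calibration).
#' @param prop_glasses Proportion flagged as wearing glasses (metadata).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 19L,
                        pfv_mean = 18, pfv_sd = 3,
                        nfv_mean = 10, nfv_sd = 2,
                        baseline_bias_mean = 0.65,
                        motor_noise_sd = 0.25,
                        prop_glasses = 0.684) {
  if (!is.finite(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1")
  }
  if (any(c(pfv_sd, nfv_sd, motor_noise_sd, baseline_bias_mean) < 0)) {
    stop("spread and bias parameters must be >= 0")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      pfv_mean = pfv_mean, pfv_sd = pfv_sd,
      nfv_mean = nfv_mean, nfv_sd = nfv_sd,
      baseline_bias_mean = baseline_bias_mean,
      motor_noise_sd = motor_noise_sd,
      prop_glasses = prop_glasses
    ),
    class = "cohort_spec"
  )
}

# Inverse-CDF sampling from N(mean, sd) truncated to (0, Inf); one uniform
# per draw keeps the RNG stream length fixed regardless of rejections.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Draw a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of [synthetic_subject()]s with ids `S001`, `S002`, ...
#' @examples
#' cohort <- sample_cohort(cohort_spec(n_subjects = 3), seed = 1)
#' sapply(cohort, function(s) s$nfv_amplitude)
#' @export
sample_cohort <- function(spec, seed) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  if (!is.finite(seed)) stop("`seed` must be a finite integer")
  set.seed(as.integer(seed))
  n <- spec$n_subjects
  pfv <- rtruncnorm_pos(n, spec$pfv_mean, spec$pfv_sd)
  nfv <- rtruncnorm_pos(n, spec$nfv_mean, spec$nfv_sd)
  glasses <- stats::runif(n) < spec$prop_glasses
  lapply(seq_len(n), function(i) {
    synthetic_subject(
      subject_id = sprintf("S%03d", i),
      pfv_amplitude = pfv[i],
      nfv_amplitude = nfv[i],
      baseline_bias_mean = spec$baseline_bias_mean,
      motor_noise_sd = spec$motor_noise_sd,
      wears_glasses = glasses[i]
    )
  })
}

#' Write / read a cohort as CSV
#'
#' Columns: `subject_id, pfv_amplitude, nfv_amplitude, baseline_bias_mean,
#' motor_noise_sd, wears_glasses`.
#'
#' @param cohort List of [synthetic_subject()]s.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a list of subjects.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    pfv_amplitude = vapply(cohort, `[[`, 0, "pfv_amplitude"),
    nfv_amplitude = vapply(cohort, `[[`, 0, "nfv_amplitude"),
    baseline_bias_mean = vapply(cohort, `[[`, 0, "baseline_bias_mean"),
    motor_noise_sd = vapply(cohort, `[[`, 0, "motor_noise_sd"),
    wears_glasses = vapply(cohort, `[[`, FALSE, "wears_glasses")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "pfv_amplitude", "nfv_amplitude",
              "baseline_bias_mean", "motor_noise_sd")
  if (!all(needed %in% names(df))) {
    stop("cohort CSV is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    synthetic_subject(
      subject_id = df$subject_id[i],
      pfv_amplitude = df$pfv_amplitude[i],
      nfv_amplitude = df$nfv_amplitude[i],
      baseline_bias_mean = df$baseline_bias_mean[i],
      motor_noise_sd = df$motor_noise_sd[i],
      wears_glasses = isTRUE(df$wears_glasses[i])
    )
  })
}
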