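test_that("constructed events always satisfy the ordering invariant", {
  ev <- truth_clean$events
  expect_true(all(with(ev, hs < ts & ts < ho & ho < to & to < hs_next)))
  expect_equal(nrow(ev), params_clean$n_strides)
  ph <- truth_clean$phases
  expect_equal(ph$lr + ph$ms + ph$ps + ph$sw, rep(100, nrow(ph)),
               tolerance = 1e-9)
})

test_that("identical seeds give bit-identical artifacts", {
  p <- gait_model_params(n_strides = 5, seed = 77)
  a <- generate_trajectory(p)
  b <- generate_trajectory(p)
  expect_identical(a$pos, b$pos)
  expect_identical(a$omega_dps, b$omega_dps)
  expect_identical(simulate_imu(a), simulate_imu(b))
  expect_identical(simulate_markers(a, 1, seed = 78),
                   simulate_markers(b, 1, seed = 78))
  co1 <- generate_cohort(cohort_spec(seed = 79))
  co2 <- generate_cohort(cohort_spec(seed = 79))
  expect_identical(co1$subjects, co2$subjects)
})

test_that("emitted acceleration is the second derivative of position", {
  # the trajectory is C2 (not C3) at the piecewise-quintic joints, so the
  # second-difference check runs between knots with a step small enough
  # for the fourth-derivative truncation error to stay below tolerance
  fn <- truth_clean$fn
  h <- 2.5e-4
  t <- seq(1.2, 9.5, by = 0.01)
  near_knot <- vapply(t, function(ti)
    any(abs(ti - truth_clean$knots) < 5 * h), logical(1))
  t <- t[!near_knot]
  num <- (fn$pos(t + h) - 2 * fn$pos(t) + fn$pos(t - h)) / h^2
  expect_lt(max(abs(num - fn$acc(t))), 1e-3)
  numv <- (fn$pos(t + h) - fn$pos(t - h)) / (2 * h)
  expect_lt(max(abs(numv - fn$vel(t))), 1e-4)
})

test_that("the foot is truly stationary over each flat-foot interval", {
  ev <- truth_clean$events
  for (k in seq_len(nrow(ev))) {
    idx <- ev$ts[k]:ev$ho[k]
    expect_lt(max(abs(truth_clean$vel[idx, ])), 1e-12)
  }
})

test_that("stationary lead-in reads gravity on the accelerometer", {
  rec <- simulate_imu(truth_noisy)
  still <- 1:30                           # lead-in before the first cycle
  gm <- sqrt(rowSums(rec$acc[still, ]^2))
  sigma <- params_noisy$noise$accel_mps2
  expect_lt(abs(mean(gm) - 9.80665), 3 * sigma / sqrt(length(still)) + 0.01)
})

test_that("zero-noise markers reproduce the true relative clearance", {
  mk <- simulate_markers(truth_clean, marker_noise_mm = 0)
  z <- normalize_reference(mk)
  z_true <- truth_clean$pos[, 3] * 1000
  expect_lt(max(abs(z - (z_true - min(z_true)))), 1e-9)
})

test_that("cohort draws respect the group structure and constraints", {
  co <- generate_cohort(cohort_spec(seed = 808))
  s <- co$subjects
  expect_equal(nrow(s), 80)
  expect_equal(sum(s$group == "HC"), 20)
  expect_true(all(abs(s$lr + s$ms + s$ps + s$sw - 100) < 1e-9))
  expect_true(all(s$min_mm <= pmin(s$max1_mm, s$max2_mm)))
  expect_true(all(s$st_s > 0.8))
  expect_length(co$params, 80)
  expect_s3_class(co$params[[1]], "gait_model_params")
  # recoverable group contrast: HC stride length exceeds FOGoff
  expect_gt(mean(s$sl_m[s$group == "HC"]),
            mean(s$sl_m[s$group == "FOGoff"]))
  expect_error(cohort_spec(groups = data.frame(group = "HC", n = 0L)),
               class = "freezekin_parameter")
})

test_that("invalid model parameters are rejected", {
  expect_error(gait_model_params(phase_fractions = c(lr = .3, ms = .3,
                                                     ps = .3, sw = .3)),
               class = "freezekin_parameter")
  expect_error(gait_model_params(clearance_profile = c(max1_mm = 100,
                                                       min_mm = 120,
                                                       max2_mm = 110)),
               class = "freezekin_parameter")
  expect_error(gait_model_params(swing_peak_dps = 10),
               class = "freezekin_parameter")
  expect_error(simulate_markers(truth_clean, marker_noise_mm = -1),
               class = "freezekin_parameter")
})

test_that("noisier sensors degrade event accuracy on average", {
  errs <- vapply(c(0, 4), function(sig) {
    p <- gait_model_params(n_strides = 8,
                           noise = list(gyro_dps = sig, accel_mps2 = 0,
                                        accel_bias_mps2 = 0), seed = 909)
    tr <- generate_trajectory(p)
    ev <- detect_from_recording(simulate_imu(tr))
    m <- match_events(ev, tr$events)
    mean(abs(as.matrix(m$det[, 2:6]) - as.matrix(m$tru[, 2:6])))
  }, numeric(1))
  expect_lte(errs[1], errs[2])
})
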