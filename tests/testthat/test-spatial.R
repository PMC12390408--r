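test_that("rotation removes gravity for static poses", {
  n <- 10
  g <- 9.80665
  # identity orientation, sensor reads +g on z
  rec <- imu_recording(t = (0:(n - 1)) / 100,
                       acc = cbind(0, 0, rep(g, n)),
                       gyr = matrix(0, n, 3),
                       quat = matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE),
                       fs = 100)
  ga <- rotate_and_degravitate(rec)
  expect_equal(max(abs(ga$a_global)), 0, tolerance = 1e-12)

  # pitched 90 deg about y: rotation matrix built directly as the oracle
  th <- pi / 2
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  f_sensor <- as.numeric(t(R) %*% c(0, 0, g))
  rec90 <- imu_recording(t = (0:(n - 1)) / 100,
                         acc = matrix(f_sensor, n, 3, byrow = TRUE),
                         gyr = matrix(0, n, 3),
                         quat = matrix(c(cos(th / 2), 0, sin(th / 2), 0),
                                       n, 4, byrow = TRUE),
                         fs = 100)
  ga90 <- rotate_and_degravitate(rec90)
  expect_equal(max(abs(ga90$a_global)), 0, tolerance = 1e-9)

  bad <- rec
  bad$quat[2, ] <- c(0.5, 0, 0, 0)
  expect_error(rotate_and_degravitate(bad), class = "freezekin_data")
})

test_that("rotated acceleration matches the generator's global truth", {
  ga <- rotate_and_degravitate(rec_clean,
                               detect_from_recording(rec_clean))
  expect_lt(max(abs(ga$a_global - truth_clean$acc)), 1e-6)
})

test_that("ZUPT zeroes flat foot exactly and detrends bias drift", {
  ev <- detect_from_recording(rec_clean)
  sp <- spatial_from_recording(rec_clean, ev)
  ff <- sp$ga$flatfoot
  for (k in seq_len(nrow(ff))) {
    expect_identical(unique(as.vector(sp$v[ff[k, 1]:ff[k, 2], ])), 0)
  }

  # constant bias b over an anchored span: raw terminal velocity b*T,
  # detrended terminal velocity 0, mid-span error <= b*T/2
  fs <- 100
  n <- 401
  b <- 0.2
  ga <- structure(list(a_global = cbind(rep(b, n), 0, 0),
                       flatfoot = rbind(c(1L, 10L), c(390L, 401L)),
                       fs = fs, n = n), class = "global_accel")
  v <- zupt_velocity(ga, fs)
  span_T <- (390 - 10) / fs
  raw <- cumtrapz(rep(b, 381), 1 / fs)
  expect_equal(raw[381], b * span_T, tolerance = 1e-9)
  expect_identical(v[390, 1], 0)
  expect_lte(max(abs(v[10:390, 1])), b * span_T / 2 + 1e-9)

  # zero acceleration -> zero velocity
  ga0 <- structure(list(a_global = matrix(0, n, 3),
                        flatfoot = rbind(c(1L, 10L)), fs = fs, n = n),
                   class = "global_accel")
  expect_identical(max(abs(zupt_velocity(ga0, fs))), 0)

  ga_noff <- structure(list(a_global = matrix(0, n, 3),
                            flatfoot = matrix(integer(0), ncol = 2),
                            fs = fs, n = n), class = "global_accel")
  expect_error(zupt_velocity(ga_noff, fs),
               class = "freezekin_zupt_impossible")
})

test_that("velocity recovery on clean strides is within 2% of peak", {
  ev <- detect_from_recording(rec_clean)
  sp <- spatial_from_recording(rec_clean, ev)
  vx_true <- truth_clean$vel[, 1]
  mid <- ev$hs[3]:ev$hs_next[8]
  rms <- sqrt(mean((sp$v[mid, 1] - vx_true[mid])^2))
  expect_lt(rms, 0.02 * max(abs(vx_true)))
})

test_that("stride length is recovered within 1% and dH never decreases", {
  ev <- detect_from_recording(rec_clean)
  sp <- spatial_from_recording(rec_clean, ev)
  sl <- sp$sl
  expect_true(any(!is.na(sl)))
  expect_equal(mean(sl, na.rm = TRUE), params_clean$stride_length_m,
               tolerance = 0.01)
  # dH is non-decreasing over each integration span (it resets to zero at
  # each flat-foot interval, so monotonicity holds from heel off onward)
  d <- attr(sp$sl, "dH")
  for (k in which(!is.na(sl))) {
    seg <- d[ev$ho[k]:(ev$hs_next[k] - 1)]
    expect_true(all(diff(seg) > -1e-12))
  }
  # stationary foot: flat foot everywhere
  n <- 200
  ga <- structure(list(a_global = matrix(0, n, 3),
                       flatfoot = rbind(c(1L, n)), fs = 100, n = n),
                  class = "global_accel")
  v0 <- zupt_velocity(ga, 100)
  ev0 <- gait_events(data.frame(stride = 1, hs = 20, ts = 40, ho = 120,
                                to = 150, hs_next = 190), fs = 100)
  expect_equal(as.numeric(stride_length(v0, ga, ev0, 100)), 0)
})

test_that("ZUPT beats naive double integration under accelerometer bias", {
  p <- gait_model_params(n_strides = 10,
                         noise = list(gyro_dps = 0, accel_mps2 = 0,
                                      accel_bias_mps2 = 0.05),
                         seed = 303)
  tr <- generate_trajectory(p)
  rec <- simulate_imu(tr)
  ev <- detect_from_recording(rec)
  sp <- spatial_from_recording(rec, ev)
  sl_naive <- stride_length_naive(sp$ga, ev)
  err_zupt <- abs(sp$sl - p$stride_length_m)
  err_naive <- abs(sl_naive - p$stride_length_m)
  ok <- !is.na(err_zupt)
  expect_true(all(err_zupt[ok] < err_naive[ok]))
})

test_that("speed is SL/ST with positive stride times", {
  expect_equal(speed(1.30, 1.00), 1.30)
  expect_equal(speed(0, 1.1), 0)
  expect_error(speed(1, 0), class = "freezekin_data")
  ev <- detect_from_recording(rec_clean)
  sp <- spatial_from_recording(rec_clean, ev)
  v <- speed(sp$sl, stride_time(ev))
  expect_equal(mean(v, na.rm = TRUE),
               params_clean$stride_length_m / params_clean$stride_time_s,
               tolerance = 0.02)
})

test_that("clearance landmarks are recovered within 5 mm, in order", {
  ev <- detect_from_recording(rec_clean)
  sp <- spatial_from_recording(rec_clean, ev)
  cl <- sp$cl
  ok <- cl$valid_max1 & cl$valid_min & cl$valid_max2
  expect_gte(sum(ok), 8)
  prof <- params_clean$clearance_profile
  expect_lt(max(abs(cl$max1_mm[ok] - prof[["max1_mm"]])), 5)
  expect_lt(max(abs(cl$min_mm[ok] - prof[["min_mm"]])), 5)
  expect_lt(max(abs(cl$max2_mm[ok] - prof[["max2_mm"]])), 5)
  expect_true(all(cl$i_max1[ok] < cl$i_min[ok]))
  expect_true(all(cl$i_min[ok] < cl$i_max2[ok]))
  expect_true(all(cl$max1_mm[ok] >= cl$min_mm[ok]))
  expect_true(all(cl$max2_mm[ok] >= cl$min_mm[ok]))
})

test_that("a flat trajectory yields no valid landmarks", {
  n <- 400
  ga <- structure(list(a_global = matrix(0, n, 3),
                       flatfoot = rbind(c(40L, 120L), c(250L, 330L)),
                       fs = 100, n = n), class = "global_accel")
  ev <- gait_events(data.frame(stride = 1, hs = 20, ts = 40, ho = 120,
                               to = 150, hs_next = 260), fs = 100)
  cl <- clearance(ga, ev, 100)
  expect_false(any(cl$valid_max1))
  expect_false(any(cl$valid_min))
})
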