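test_that("reference normalization subtracts the absolute minimum", {
  expect_equal(normalize_reference(c(105, 100, 130)), c(5, 0, 30))
  expect_equal(normalize_reference(rep(42, 5)), rep(0, 5))
  markers <- simulate_markers(truth_clean, marker_noise_mm = 0)
  z <- normalize_reference(markers)
  z_true <- truth_clean$pos[, 3] * 1000
  expect_lt(max(abs(z - (z_true - min(z_true)))), 1e-9)
})

test_that("landmark pairing counts pairs and logs exclusions", {
  imu <- data.frame(stride = 1:3,
                    max1_mm = c(150, 148, 151), min_mm = c(90, 91, 89),
                    max2_mm = c(120, 119, 121),
                    valid_max1 = TRUE, valid_min = TRUE, valid_max2 = TRUE)
  ev <- detect_from_recording(rec_clean)[1:3, ]
  ref <- normalize_reference(simulate_markers(truth_clean,
                                              marker_noise_mm = 0))
  pairs <- pair_landmarks(imu, ref, ev)
  expect_equal(nrow(pairs), 9)
  imu$valid_min[2] <- FALSE
  pairs8 <- pair_landmarks(imu, ref, ev)
  expect_equal(nrow(pairs8), 8)
  expect_equal(attr(pairs8, "n_excluded"), 1L)
  expect_error(pair_landmarks(imu[1:2, ], ref, ev),
               class = "freezekin_alignment")
})

test_that("error metrics follow the absolute / relative definitions", {
  p <- data.frame(x_os = 100, x_imu = 95)
  em <- error_metrics(p)
  expect_equal(em$eabs_mean, 5)
  expect_equal(em$erel_mean, 5)
  same <- data.frame(x_os = c(80, 90), x_imu = c(80, 90))
  em0 <- error_metrics(same)
  expect_equal(em0$eabs_mean, 0)
  expect_equal(em0$erel_mean, 0)
  two <- data.frame(x_os = c(100, 200), x_imu = c(95, 210))
  em2 <- error_metrics(two)
  expect_equal(em2$eabs_mean, 7.5)
  expect_equal(em2$erel_mean, 5)
  withz <- data.frame(x_os = c(100, 0), x_imu = c(95, 5))
  expect_warning(error_metrics(withz), class = "freezekin_warning")
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  same <- data.frame(x_os = c(80, 90, 100), x_imu = c(80, 90, 100))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  d123 <- data.frame(x_os = c(0, 0, 0), x_imu = c(1, 2, 3))
  ba <- bland_altman(d123)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  # IMU uniformly 5 below reference: negative bias = underestimation
  low <- data.frame(x_os = c(100, 120, 140), x_imu = c(95, 115, 135))
  expect_equal(bland_altman(low)$bias, -5)
  expect_error(bland_altman(low[1, ]), class = "freezekin_parameter")
})

test_that("agreement agrees with a brute-force oracle on random pairs", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    p <- data.frame(x_os = runif(n, 50, 200), x_imu = runif(n, 50, 200))
    em <- error_metrics(p)
    ba <- bland_altman(p)
    # oracle: recompute from first principles, element by element
    e <- abs(p$x_os - p$x_imu)
    r <- e / abs(p$x_os) * 100
    d <- p$x_imu - p$x_os
    m <- sum(d) / n
    s2 <- sum((d - m)^2) / (n - 1)
    expect_equal(em$eabs_mean, sum(e) / n)
    expect_equal(em$eabs_sd, sqrt(sum((e - sum(e) / n)^2) / (n - 1)))
    expect_equal(em$erel_mean, sum(r) / n)
    expect_equal(ba$bias, m)
    expect_equal(ba$loa_low, m - 1.96 * sqrt(s2))
    expect_equal(ba$loa_high, m + 1.96 * sqrt(s2))
    # symmetry properties
    sw <- data.frame(x_os = p$x_imu, x_imu = p$x_os)
    expect_equal(bland_altman(sw)$bias, -ba$bias)
    expect_equal(error_metrics(sw)$eabs_mean, em$eabs_mean)
  }
})

test_that("1 mm of landmark noise leaves sub-millimetre bias, 30 strides", {
  # statistical property of the agreement stage: with measurement noise
  # of SD sigma on one side, bias tends to 0 and the limits-of-agreement
  # width to 2 * 1.96 * sigma as the stride count grows
  set.seed(406)
  sigma <- 1
  truth_vals <- rep(c(150, 90, 120), each = 30)
  pairs <- data.frame(x_os = truth_vals + rnorm(90, sd = sigma),
                      x_imu = truth_vals)
  ba <- bland_altman(pairs)
  expect_lt(abs(ba$bias), 1)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sigma,
               tolerance = 0.15)
})

test_that("the full chain vs noisy markers stays within systematics", {
  p <- gait_model_params(n_strides = 30, noise = noise_free, seed = 404)
  tr <- generate_trajectory(p)
  markers <- simulate_markers(tr, marker_noise_mm = 1, seed = 405)
  res <- validate_clearance(simulate_imu(tr), markers)
  expect_equal(nrow(res$report), 3)
  # IMU integration systematics are ~2 mm; marker normalization after
  # smoothing adds well under 1 mm
  expect_lt(max(abs(res$report$bias)), 5)
  expect_true(all(res$report$loa_low <= res$report$bias &
                  res$report$bias <= res$report$loa_high))
})
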