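test_that("noise-free synthetic strides are recovered within one sample", {
  ev <- detect_from_recording(rec_clean)
  m <- match_events(ev, truth_clean$events)
  for (col in c("hs", "ts", "ho", "to", "hs_next")) {
    expect_lte(max(abs(m$det[[col]] - m$tru[[col]])), 1)
  }
  expect_true(all(with(ev, hs < ts & ts < ho & ho < to & to < hs_next)))
})

test_that("events under 2 deg/s gyro noise stay within two samples", {
  ev <- detect_from_recording(rec_noisy)
  m <- match_events(ev, truth_noisy$events)
  errs <- unlist(lapply(c("hs", "ts", "ho", "to", "hs_next"),
                        function(col) abs(m$det[[col]] - m$tru[[col]])))
  expect_gte(mean(errs <= 2), 0.95)
})

test_that("degenerate signals raise NoStridesFound", {
  expect_error(find_stride_windows(rep(0, 1000), 100),
               class = "freezekin_no_strides")
  one_peak <- c(rep(0, 450), 300 * sin(seq(0, pi, length.out = 100)),
                rep(0, 450))
  expect_error(find_stride_windows(one_peak, 100),
               class = "freezekin_no_strides")
})

test_that("detection is translation-equivariant", {
  m <- 37L
  omega <- butterworth_lowpass(rec_clean$gyr[, 2], 3, 2, 100)
  shifted <- c(rep(omega[1], m), omega)
  ev0 <- detect_events(omega, find_stride_windows(omega, 100), fs = 100)
  ev1 <- detect_events(shifted, find_stride_windows(shifted, 100),
                       fs = 100)
  common <- seq_len(min(nrow(ev0), nrow(ev1)))
  for (col in c("hs", "ts", "ho", "to", "hs_next")) {
    expect_equal(ev1[[col]][common], ev0[[col]][common] + m)
  }
})

test_that("a piecewise-linear threshold crossing is hit exactly", {
  # |omega| crosses 30 downward exactly at sample 37 after a heel-strike
  # hump at 20; heel-off crossing on the way up to the toe-off hump at 80
  fs <- 100
  sig <- c(seq(0, 120, length.out = 20),          # heel-strike peak at 20
           seq(120, 30, length.out = 18)[-1],     # |omega| = 30 at 37
           rep(5, 25),
           seq(5, 150, length.out = 18),          # toe-off hump
           seq(150, 5, length.out = 20))
  # append a second cycle so hs_next exists
  sig2 <- c(sig, sig)
  windows2 <- structure(data.frame(start = c(1L, length(sig)),
                                   end = c(length(sig), length(sig2))),
                        sign = 1,
                        class = c("stride_windows", "data.frame"))
  ev <- detect_events(sig2, windows2, threshold_dps = 30, fs = fs)
  expect_equal(ev$ts[1], 37)
  expect_equal(ev$hs[1], 20)
})

test_that("central-stride selection keeps the middle of each bout", {
  # 14 equal strides, one segment: the middle 10 are strides 3..12
  hs <- seq(100, by = 120, length.out = 15)
  df <- data.frame(stride = 1:14, hs = hs[1:14], ts = hs[1:14] + 12,
                   ho = hs[1:14] + 60, to = hs[1:14] + 78,
                   hs_next = hs[2:15])
  ev <- gait_events(df, fs = 100)
  sel <- select_central_strides(ev, list(c(0, 2000)), 10)
  expect_equal(sel$hs, df$hs[3:12])

  # exactly n strides: all kept
  sel_all <- select_central_strides(ev[1:10, ], list(c(0, 2000)), 10)
  expect_equal(nrow(sel_all), 10)

  # two bouts of 12 -> 20 strides total
  hs2 <- seq(3000, by = 120, length.out = 13)
  df2 <- data.frame(stride = 1:12, hs = hs2[1:12], ts = hs2[1:12] + 12,
                    ho = hs2[1:12] + 60, to = hs2[1:12] + 78,
                    hs_next = hs2[2:13])
  both <- gait_events(rbind(df[1:12, ], df2), fs = 100)
  sel2 <- select_central_strides(both, list(c(0, 2000), c(2900, 4700)), 10)
  expect_equal(nrow(sel2), 20)

  # fewer than requested: all kept with a warning
  expect_warning(select_central_strides(ev[1:4, ], list(c(0, 2000)), 10),
                 class = "freezekin_warning")
  expect_error(select_central_strides(ev, list()),
               class = "freezekin_parameter")
})

test_that("event ordering is enforced by the container", {
  df <- data.frame(stride = 1, hs = 10, ts = 5, ho = 20, to = 30,
                   hs_next = 40)
  expect_error(gait_events(df, fs = 100), class = "freezekin_data")
})
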