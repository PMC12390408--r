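# shared fixtures: built once per test run, all seeded

noise_free <- list(gyro_dps = 0, accel_mps2 = 0, accel_bias_mps2 = 0)

params_clean <- gait_model_params(n_strides = 10, noise = noise_free,
                                  seed = 101)
truth_clean <- generate_trajectory(params_clean)
rec_clean <- simulate_imu(truth_clean)

params_noisy <- gait_model_params(n_strides = 10, seed = 202)
truth_noisy <- generate_trajectory(params_noisy)
rec_noisy <- simulate_imu(truth_noisy)

# match detected strides to truth strides by nearest heel strike
match_events <- function(detected, truth) {
  idx <- vapply(truth$hs, function(h) which.min(abs(detected$hs - h)),
                integer(1L))
  list(det = detected[idx, ], tru = truth)
}

# run preprocessing + event detection the way the pipeline does
detect_from_recording <- function(rec, config = pipeline_config()) {
  omega <- butterworth_lowpass(rec$gyr[, 2L], config$gyro_cutoff_hz,
                               config$filter_order, rec$fs)
  windows <- find_stride_windows(omega, rec$fs,
                                 min_stride_s = config$min_stride_s,
                                 max_stride_s = config$max_stride_s,
                                 prominence_dps = config$swing_prominence_dps)
  detect_events(omega, windows, threshold_dps = config$ts_ho_threshold_dps,
                fs = rec$fs, foot = rec$foot)
}

# spatial stage on a recording given events
spatial_from_recording <- function(rec, events, config = pipeline_config()) {
  acc_f <- apply(rec$acc, 2L, butterworth_lowpass,
                 cutoff = config$accel_cutoff_hz,
                 order = config$filter_order, fs = rec$fs)
  ga <- rotate_and_degravitate(rec, events, gravity = config$gravity_mps2,
                               acc = acc_f)
  v <- zupt_velocity(ga)
  list(ga = ga, v = v,
       sl = stride_length(v, ga, events),
       cl = clearance(ga, events, v = v))
}

# random valid event table for property tests
random_events <- function(n_strides, fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hs <- cumsum(c(10L, sample(80:140, n_strides, replace = TRUE)))
  rows <- lapply(seq_len(n_strides), function(k) {
    dur <- hs[k + 1L] - hs[k]
    cuts <- sort(sample(seq_len(dur - 1L), 3L))
    data.frame(stride = k, hs = hs[k], ts = hs[k] + cuts[1L],
               ho = hs[k] + cuts[2L], to = hs[k] + cuts[3L],
               hs_next = hs[k + 1L])
  })
  gait_events(do.call(rbind, rows), fs = fs)
}
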