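#' Run the full gait pipeline on one IMU trial
#'
#' Preconditioning (zero-phase Butterworth low-pass, 3 Hz gyroscope /
#' 10 Hz accelerometer by default), stride-window delimitation, gait-event
#' detection, optional central-stride selection, temporal parameters
#' (stride time, phase percentages, cadence) and spatial parameters
#' (ZUPT stride length, speed, clearance landmarks).
#'
#' @param rec An [imu_recording()].
#' @param config A [pipeline_config()].
#' @param segments Optional list of `c(start, end)` walking-bout sample
#'   boundaries for [select_central_strides()]; `NULL` analyzes all
#'   detected strides.
#' @return An object of class `gait_analysis`: list with `events`, the
#'   per-stride table `strides` (columns `stride`, `foot`, `hs`, `ts`,
#'   `ho`, `to`, `hs_next`, `st_s`, `lr`, `ms`, `ps`, `sw`, `sl_m`,
#'   `sp_mps`, `max1_mm`, `min_mm`, `max2_mm` and validity flags),
#'   `cadence_spm`, `clearance_mm` (the displacement series) and `config`.
#' @export
extract_gait_metrics <- function(rec, config = pipeline_config(),
                                 segments = NULL) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(config, "pipeline_config"))
  omega <- butterworth_lowpass(rec$gyr[, 2L], config$gyro_cutoff_hz,
                               config$filter_order, rec$fs)
  acc_f <- apply(rec$acc, 2L, butterworth_lowpass,
                 cutoff = config$accel_cutoff_hz,
                 order = config$filter_order, fs = rec$fs)
  windows <- find_stride_windows(omega, rec$fs,
                                 min_stride_s = config$min_stride_s,
                                 max_stride_s = config$max_stride_s,
                                 prominence_dps = config$swing_prominence_dps)
  events <- detect_events(omega, windows,
                          threshold_dps = config$ts_ho_threshold_dps,
                          fs = rec$fs, foot = rec$foot)
  if (!is.null(segments)) {
    events <- select_central_strides(events, segments,
                                     config$n_central_strides)
  }
  st <- stride_time(events)
  phases <- gait_phases(events)
  ca <- cadence(events, gait_duration(events))
  ga <- rotate_and_degravitate(rec, events, gravity = config$gravity_mps2,
                               acc = acc_f)
  v <- zupt_velocity(ga)
  sl <- stride_length(v, ga, events)
  cl <- clearance(ga, events, v = v)
  strides <- data.frame(stride = events$stride,
                        foot = attr(events, "foot"),
                        hs = events$hs, ts = events$ts, ho = events$ho,
                        to = events$to, hs_next = events$hs_next,
                        st_s = st,
                        lr = phases$lr, ms = phases$ms, ps = phases$ps,
                        sw = phases$sw,
                        sl_m = as.numeric(sl), sp_mps = as.numeric(sl) / st,
                        max1_mm = cl$max1_mm, min_mm = cl$min_mm,
                        max2_mm = cl$max2_mm,
                        valid_sl = !is.na(sl),
                        valid_max1 = cl$valid_max1,
                        valid_min = cl$valid_min,
                        valid_max2 = cl$valid_max2)
  structure(list(events = events, strides = strides, cadence_spm = ca,
                 clearance_mm = attr(cl, "clearance_mm"),
                 config = config),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  s <- x$strides
  cat(sprintf("<gait_analysis> %d stride(s), cadence %d strides/min\n",
              nrow(s), x$cadence_spm))
  cat(sprintf("  ST %.3f +/- %.3f s | SL %.3f +/- %.3f m | SP %.3f m/s\n",
              mean(s$st_s), stats::sd(s$st_s),
              mean(s$sl_m, na.rm = TRUE), stats::sd(s$sl_m, na.rm = TRUE),
              mean(s$sp_mps, na.rm = TRUE)))
  cat(sprintf("  phases LR/MS/PS/SW: %.1f / %.1f / %.1f / %.1f %%\n",
              mean(s$lr), mean(s$ms), mean(s$ps), mean(s$sw)))
  cat(sprintf("  clearance Max1/Min/Max2: %.0f / %.0f / %.0f mm\n",
              mean(s$max1_mm, na.rm = TRUE), mean(s$min_mm, na.rm = TRUE),
              mean(s$max2_mm, na.rm = TRUE)))
  invisible(x)
}

#' Write the per-stride metrics table
#' @param analysis A [extract_gait_metrics()] result.
#' @param path Output path (CSV).
#' @return The path, invisibly.
#' @export
write_gait_metrics <- function(analysis, path) {
  stopifnot(inherits(analysis, "gait_analysis"))
  utils::write.csv(analysis$strides, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate IMU clearance against a reference trajectory
#'
#' Runs the pipeline on the IMU recording, normalizes the reference
#' marker trajectory to a clearance series, pairs the per-stride
#' landmarks and reports per-landmark error metrics and Bland-Altman
#' agreement.
#'
#' @param rec An [imu_recording()].
#' @param ref A [reference_trajectory()] on the same (synchronized) time
#'   base.
#' @param config A [pipeline_config()].
#' @param ref_smooth_cutoff_hz Zero-phase low-pass applied to the marker
#'   vertical component before normalization (default 10 Hz; `NULL`
#'   disables). Necessary because subtracting the absolute minimum of an
#'   unsmoothed noisy track offsets the whole clearance series by the
#'   expected minimum of the noise (about +3.3 SD over a long flat-foot
#'   record).
#' @return List with `analysis` ([extract_gait_metrics()] result),
#'   `pairs` ([pair_landmarks()]) and `report` ([agreement_report()]).
#' @export
validate_clearance <- function(rec, ref, config = pipeline_config(),
                               ref_smooth_cutoff_hz = 10) {
  analysis <- extract_gait_metrics(rec, config)
  z_ref <- ref$pos[, match(ref$vertical_axis, c("x", "y", "z"))]
  if (!is.null(ref_smooth_cutoff_hz)) {
    fs_ref <- 1 / stats::median(diff(ref$t))
    z_ref <- butterworth_lowpass(z_ref, ref_smooth_cutoff_hz,
                                 config$filter_order, fs_ref)
  }
  ref_cl <- normalize_reference(z_ref)
  imu <- analysis$strides
  imu_cl <- data.frame(stride = imu$stride, max1_mm = imu$max1_mm,
                       min_mm = imu$min_mm, max2_mm = imu$max2_mm,
                       valid_max1 = imu$valid_max1,
                       valid_min = imu$valid_min,
                       valid_max2 = imu$valid_max2)
  pairs <- pair_landmarks(imu_cl, ref_cl, analysis$events)
  list(analysis = analysis, pairs = pairs, report = agreement_report(pairs))
}
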