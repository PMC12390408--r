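# --- C2 compact bump primitives -------------------------------------------
# b(u) = 64 u^3 (1-u)^3 on [0,1] (peak 1 at u = 1/2), zero outside; it and
# its first two derivatives vanish at the support edges, so sums of bumps
# are C2 and acceleration is well defined everywhere.
bump <- function(u) ifelse(u > 0 & u < 1, 64 * u^3 * (1 - u)^3, 0)

# quintic smoothstep and derivatives: zero velocity AND acceleration at
# both ends, so piecewise segments joined at knots are C2 and every knot
# with a value extremum is a true local extremum of the curve.
sstep <- function(u) {
  uu <- pmin(pmax(u, 0), 1)
  6 * uu^5 - 15 * uu^4 + 10 * uu^3
}
sstep_d1 <- function(u) ifelse(u > 0 & u < 1, 30 * u^2 * (1 - u)^2, 0)
sstep_d2 <- function(u) ifelse(u > 0 & u < 1, 60 * u * (1 - u) * (1 - 2 * u), 0)

# u (in (0.5, 1)) where bump(u) = r, i.e. the downward crossing of level r
bump_cross <- function(r) {
  stopifnot(r > 0, r < 1)
  stats::uniroot(function(u) 64 * u^3 * (1 - u)^3 - r,
                 c(0.5 + 1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# half-width of a stance hump such that, AFTER the band-limiting the
# emitted channel and the analysis filter apply (two zero-phase passes),
# the |omega| threshold crossing sits offset_target seconds from the hump
# centre. Fixed-point iteration on an isolated bump.
calibrate_hump_width <- function(amp, offset_target, thr, cutoff, fs_hr) {
  for (raise in 1:12) {
    u_star <- bump_cross(min(thr / amp, 0.99))
    w <- offset_target / (2 * (u_star - 0.5))
    ok <- TRUE
    for (iter in 1:6) {
      half_span <- 4 * w + 2 / cutoff
      n <- ceiling(2 * half_span * fs_hr) + 1L
      t <- (seq_len(n) - 1L) / fs_hr
      y <- amp * bump((t - (half_span - w)) / (2 * w))
      y2 <- butterworth_lowpass(butterworth_lowpass(y, cutoff, 2L, fs_hr),
                                cutoff, 2L, fs_hr)
      ipk <- which.max(y2)
      if (y2[ipk] < 1.25 * thr) { ok <- FALSE; break }
      below <- which(y2[ipk:n] <= thr)
      offset_actual <- (below[1L] - 1L) / fs_hr
      if (abs(offset_actual - offset_target) < 0.25 / fs_hr) break
      w <- w * offset_target / offset_actual
    }
    if (ok) return(list(w = w, amp = amp))
    # a sharper (shorter) phase needs a stronger pulse to survive the
    # band limit; raise the amplitude and retry
    amp <- amp * 1.4
    if (amp > 2000) break
  }
  fk_stop("stance hump cannot clear the event threshold after band-limiting",
          "parameter")
}

#' Synthetic gait model parameters
#'
#' Parameter set of the ground-truthed synthetic gait generator. Defaults
#' describe a healthy adult walking at self-selected speed recorded at
#' 100 Hz: 1.05 s stride time; four-phase split of 10.5/40/14.5/35 percent
#' (loading response / midstance / pre-swing / swing); 1.30 m stride
#' length; an instep clearance profile with Max1 150 mm, Min 90 mm, Max2
#' 120 mm; a dominant mid-swing sagittal angular-velocity peak of
#' 400 deg/s with stance-adjacent heel-strike and push-off humps of 120
#' and 200 deg/s. Default sensor imperfections are white gyroscope noise
#' of 2 deg/s, white accelerometer noise of 0.05 m/s^2 and no
#' accelerometer bias (bias is injected explicitly in drift experiments).
#'
#' @param stride_time_s Stride time, s.
#' @param phase_fractions Named fractions `lr`, `ms`, `ps`, `sw` summing
#'   to 1.
#' @param stride_length_m Stride length, m.
#' @param clearance_profile Named vector `max1_mm`, `min_mm`, `max2_mm`.
#' @param swing_peak_dps Dominant mid-swing angular-velocity magnitude,
#'   deg/s.
#' @param hs_peak_dps,to_peak_dps Stance-adjacent hump amplitudes, deg/s.
#' @param noise List with `gyro_dps`, `accel_mps2`, `accel_bias_mps2`.
#' @param n_strides Number of ground-truthed strides.
#' @param fs Sampling rate, Hz.
#' @param threshold_dps Threshold whose crossings define toe strike / heel
#'   off; the template is engineered so the crossings land at the nominal
#'   phase boundaries.
#' @param gyro_cutoff_hz Band limit applied to the emitted gyroscope
#'   template (matches the analysis filter, so the detection rules recover
#'   the constructed events).
#' @param pitch_pushoff_deg,pitch_swing_deg Amplitudes of the sagittal
#'   foot-pitch profile carried by the quaternion stream: plantarflexion
#'   around push-off (negative) and dorsiflexion in late swing.
#' @param lead_s Quiet lead-in before the first heel strike, s.
#' @param res_factor Internal oversampling factor for ground-truth event
#'   measurement.
#' @param seed Integer seed driving all of the generator's randomness.
#' @return An object of class `gait_model_params`.
#' @export
gait_model_params <- function(stride_time_s = 1.05,
                              phase_fractions = c(lr = 0.105, ms = 0.40,
                                                  ps = 0.145, sw = 0.35),
                              stride_length_m = 1.30,
                              clearance_profile = c(max1_mm = 150,
                                                    min_mm = 90,
                                                    max2_mm = 120),
                              swing_peak_dps = 400,
                              hs_peak_dps = 120,
                              to_peak_dps = 200,
                              noise = list(gyro_dps = 2,
                                           accel_mps2 = 0.05,
                                           accel_bias_mps2 = 0),
                              n_strides = 10L,
                              fs = 100,
                              threshold_dps = 30,
                              gyro_cutoff_hz = 3,
                              pitch_pushoff_deg = -55,
                              pitch_swing_deg = 20,
                              lead_s = 0.5,
                              res_factor = 10L,
                              seed = NULL) {
  pf <- phase_fractions[c("lr", "ms", "ps", "sw")]
  if (any(is.na(pf)) || any(pf <= 0) || abs(sum(pf) - 1) > 1e-9) {
    fk_stop("phase_fractions must be positive, named lr/ms/ps/sw and sum to 1",
            "parameter")
  }
  cl <- clearance_profile[c("max1_mm", "min_mm", "max2_mm")]
  if (any(is.na(cl)) || any(cl <= 0) ||
      cl[["min_mm"]] > min(cl[["max1_mm"]], cl[["max2_mm"]])) {
    fk_stop("clearance profile needs min_mm <= max1_mm and <= max2_mm",
            "parameter")
  }
  if (stride_time_s <= 0 || stride_length_m < 0 || fs <= 0 ||
      n_strides < 1L) {
    fk_stop("dimensional parameters must be positive", "parameter")
  }
  if (swing_peak_dps <= threshold_dps || hs_peak_dps <= threshold_dps ||
      to_peak_dps <= threshold_dps) {
    fk_stop("peak amplitudes must exceed the event threshold", "parameter")
  }
  noise <- utils::modifyList(list(gyro_dps = 0, accel_mps2 = 0,
                                  accel_bias_mps2 = 0), as.list(noise))
  if (any(unlist(noise[c("gyro_dps", "accel_mps2")]) < 0)) {
    fk_stop("noise standard deviations must be non-negative", "parameter")
  }
  p <- list(stride_time_s = stride_time_s, phase_fractions = pf,
            stride_length_m = stride_length_m, clearance_profile = cl,
            swing_peak_dps = swing_peak_dps, hs_peak_dps = hs_peak_dps,
            to_peak_dps = to_peak_dps, noise = noise,
            n_strides = as.integer(n_strides), fs = fs,
            threshold_dps = threshold_dps, gyro_cutoff_hz = gyro_cutoff_hz,
            pitch_pushoff_deg = pitch_pushoff_deg,
            pitch_swing_deg = pitch_swing_deg,
            lead_s = lead_s, res_factor = as.integer(res_factor),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  # hump half-widths calibrated so that, after the band-limiting of the
  # emitted channel plus the analysis filter, the threshold crossings land
  # on the nominal toe-strike / heel-off instants
  T <- stride_time_s
  fs_hr <- fs * p$res_factor
  cal_hs <- calibrate_hump_width(hs_peak_dps, pf[["lr"]] * T,
                                 threshold_dps, gyro_cutoff_hz, fs_hr)
  cal_to <- calibrate_hump_width(to_peak_dps, pf[["ps"]] * T,
                                 threshold_dps, gyro_cutoff_hz, fs_hr)
  p$w_hs <- cal_hs$w
  p$w_to <- cal_to$w
  p$hs_peak_dps <- cal_hs$amp            # effective (possibly raised)
  p$to_peak_dps <- cal_to$amp
  # dominant swing lobe: supported on the central 70% of swing so it never
  # displaces the stance-adjacent peaks
  p$w_sw <- 0.35 * pf[["sw"]] * T
  if (p$lead_s < p$w_hs + 0.05) {
    fk_stop("lead_s too short for the first heel-strike hump", "parameter")
  }
  structure(p, class = "gait_model_params")
}

# nominal event times (s) for cycles 0 .. n+2 (the last cycle only feeds
# the "next heel strike" lookups); array index c corresponds to cycle c-1
nominal_events <- function(p) {
  T <- p$stride_time_s
  pf <- p$phase_fractions
  hs <- p$lead_s + (0:(p$n_strides + 2L)) * T
  list(hs = hs, ts = hs + pf[["lr"]] * T,
       ho = hs + (pf[["lr"]] + pf[["ms"]]) * T,
       to = hs + (pf[["lr"]] + pf[["ms"]] + pf[["ps"]]) * T)
}

#' Generate a ground-truthed synthetic foot trajectory
#'
#' Builds a continuous, twice-differentiable model of one foot over
#' `n_strides` gait cycles plus lead-in/lead-out context:
#' \itemize{
#'   \item the foot is stationary from each heel strike to the following
#'     heel off (covering the detected flat-foot interval);
#'   \item horizontal displacement advances `stride_length_m` per cycle
#'     along a quintic smoothstep over heel off to the next heel strike;
#'   \item the vertical profile is a piecewise quintic through the
#'     clearance landmarks (Max1, Min, Max2) during swing, returning to
#'     the flat-foot baseline at the next toe strike;
#'   \item the sagittal angular velocity is a sum of compact C2 bumps:
#'     maxima at heel strike and toe off, a dominant opposite-signed
#'     mid-swing lobe (physical sign convention: mid-swing positive), with
#'     amplitudes balancing to zero net rotation per cycle.
#' }
#' The emitted gyroscope channel is band-limited with the same zero-phase
#' Butterworth response the analysis applies, and the ground-truth event
#' indices are measured from that band-limited template at high
#' resolution, so the detection rules recover the constructed events.
#'
#' @param params A [gait_model_params()] object.
#' @return An object of class `gait_truth`: list with `params`, `events`
#'   (truth [gait_events()] at `fs`), `phases` (truth phase percentages),
#'   `sl_m`, `landmarks` (truth clearance landmarks, mm), sampled streams
#'   `t`, `pos`, `vel`, `acc` (global frame, m), `omega_dps` (band-limited
#'   sagittal angular velocity), `theta_deg` (foot pitch), and the
#'   analytic closures `fn` (`pos`, `vel`, `acc`, `omega_raw`, `theta`).
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "gait_model_params"))
  p <- params
  ev <- nominal_events(p)
  n_cyc <- p$n_strides + 2L              # modelled cycles 0 .. n+1
  idx <- seq_len(n_cyc)
  T <- p$stride_time_s
  sw_dur <- p$phase_fractions[["sw"]] * T
  msw <- (ev$to[idx] + ev$hs[idx + 1L]) / 2   # mid-swing instants

  # --- sagittal angular velocity (physical sign: mid-swing positive) ----
  # band-limiting shifts the realized peaks and threshold crossings a few
  # hundredths of a second from the nominal instants (as it does in real
  # filtered gait data); ground truth is therefore MEASURED on the
  # band-limited template rather than asserted from the nominal geometry
  make_bumps <- function(d_hs, d_to, w_hs, w_to) data.frame(
    center = c(ev$hs[idx] + d_hs, ev$to[idx] + d_to, msw),
    halfw = c(rep(w_hs, n_cyc), rep(w_to, n_cyc), rep(p$w_sw, n_cyc)),
    amp = c(rep(-p$hs_peak_dps, n_cyc), rep(-p$to_peak_dps, n_cyc),
            rep(p$swing_peak_dps, n_cyc)))
  make_omega <- function(bumps) function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(bumps))) {
      lo <- bumps$center[i] - bumps$halfw[i]
      sel <- which(t > lo & t < lo + 2 * bumps$halfw[i])
      if (length(sel)) {
        out[sel] <- out[sel] +
          bumps$amp[i] * bump((t[sel] - lo) / (2 * bumps$halfw[i]))
      }
    }
    out
  }
  # foot pitch, deg: independent bounded sagittal profile - zero on the
  # flat foot, plantarflexion around push-off, dorsiflexion in late swing
  # settling back to zero by the next toe strike. (The gyroscope template
  # above is engineered for event-detection morphology and is not the
  # exact derivative of this profile; the pipeline never cross-integrates
  # the two streams.)
  pitch_bumps <- do.call(rbind, lapply(idx, function(c) {
    plant_lo <- ev$ho[c]
    plant_hi <- ev$to[c] + 0.6 * sw_dur
    dorsi_lo <- msw[c]
    dorsi_hi <- ev$ts[c + 1L]
    data.frame(center = c((plant_lo + plant_hi) / 2,
                          (dorsi_lo + dorsi_hi) / 2),
               halfw = c((plant_hi - plant_lo) / 2,
                         (dorsi_hi - dorsi_lo) / 2),
               amp = c(p$pitch_pushoff_deg, p$pitch_swing_deg))
  }))
  theta_fun <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(pitch_bumps))) {
      lo <- pitch_bumps$center[i] - pitch_bumps$halfw[i]
      sel <- which(t > lo & t < lo + 2 * pitch_bumps$halfw[i])
      if (length(sel)) {
        out[sel] <- out[sel] + pitch_bumps$amp[i] *
          bump((t[sel] - lo) / (2 * pitch_bumps$halfw[i]))
      }
    }
    out
  }

  # --- horizontal motion: quintic span heel off -> next heel strike -----
  x_spans <- data.frame(from = ev$ho[idx], to = ev$hs[idx + 1L])
  piecewise3 <- function(t, spans, vals_from, vals_to, deriv = 0L) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(spans))) {
      a <- spans$from[i]; b <- spans$to[i]; dt <- b - a
      if (deriv == 0L) {
        sel <- which(t >= b)
        out[sel] <- out[sel] + (vals_to[i] - vals_from[i])
        sel <- which(t > a & t < b)
        if (length(sel)) {
          out[sel] <- out[sel] +
            (vals_to[i] - vals_from[i]) * sstep((t[sel] - a) / dt)
        }
      } else {
        sel <- which(t > a & t < b)
        if (length(sel)) {
          d <- if (deriv == 1L) sstep_d1((t[sel] - a) / dt) / dt
               else sstep_d2((t[sel] - a) / dt) / dt^2
          out[sel] <- out[sel] + (vals_to[i] - vals_from[i]) * d
        }
      }
    }
    out
  }
  SL <- p$stride_length_m
  x_fun <- function(t, deriv = 0L) {
    piecewise3(t, x_spans, rep(0, n_cyc), rep(SL, n_cyc), deriv)
  }

  # --- vertical motion: piecewise quintic through clearance landmarks ---
  cl <- p$clearance_profile / 1000   # m
  z_knots_t <- function(c) {
    to_c <- ev$to[c]
    c(ev$ho[c],
      to_c + 0.25 * sw_dur, to_c + 0.55 * sw_dur, to_c + 0.85 * sw_dur,
      if (c + 1L <= length(ev$ts)) ev$ts[c + 1L] else to_c + sw_dur +
        p$phase_fractions[["lr"]] * T)
  }
  z_vals <- c(0, cl[["max1_mm"]], cl[["min_mm"]], cl[["max2_mm"]], 0)
  z_segments <- do.call(rbind, lapply(seq_len(n_cyc), function(c) {
    kt <- z_knots_t(c)
    data.frame(from = kt[-5L], to = kt[-1L],
               v0 = z_vals[-5L], v1 = z_vals[-1L])
  }))
  z_fun <- function(t, deriv = 0L) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(z_segments))) {
      a <- z_segments$from[i]; b <- z_segments$to[i]; dt <- b - a
      sel <- which(t >= a & t < b)
      if (!length(sel)) next
      u <- (t[sel] - a) / dt
      out[sel] <- out[sel] + switch(deriv + 1L,
        z_segments$v0[i] + (z_segments$v1[i] - z_segments$v0[i]) * sstep(u),
        (z_segments$v1[i] - z_segments$v0[i]) * sstep_d1(u) / dt,
        (z_segments$v1[i] - z_segments$v0[i]) * sstep_d2(u) / dt^2)
    }
    out
  }

  fn <- list(
    pos = function(t) cbind(x = x_fun(t), y = 0 * t, z = z_fun(t)),
    vel = function(t) cbind(x = x_fun(t, 1L), y = 0 * t, z = z_fun(t, 1L)),
    acc = function(t) cbind(x = x_fun(t, 2L), y = 0 * t, z = z_fun(t, 2L)),
    omega_raw = NULL,                    # filled after centre calibration
    theta = theta_fun)

  # --- sample grids ------------------------------------------------------
  t_end <- msw[n_cyc] + p$w_sw + 0.2
  res <- p$res_factor
  fs_hr <- p$fs * res
  n_hr <- floor(t_end * fs_hr) + 1L
  t_hr <- (seq_len(n_hr) - 1L) / fs_hr
  thr <- p$threshold_dps
  # ground-truth events live on the twice-filtered template: the analysis
  # filters the emitted (once-filtered) channel a second time
  s <- NULL
  argmax_near <- function(t0, halfw) {
    lo <- max(1L, floor((t0 - halfw) * fs_hr) + 1L)
    hi <- min(n_hr, ceiling((t0 + halfw) * fs_hr) + 1L)
    lo + which.max(s[lo:hi]) - 1L
  }
  w_hs <- p$w_hs; w_to <- p$w_to
  omega_raw <- make_omega(make_bumps(0, 0, w_hs, w_to))
  omega_sm_hr <- butterworth_lowpass(omega_raw(t_hr), p$gyro_cutoff_hz,
                                     2L, fs_hr)
  omega_sm2 <- butterworth_lowpass(omega_sm_hr, p$gyro_cutoff_hz, 2L,
                                   fs_hr)
  s <- -omega_sm2                       # oriented: stance maxima positive
  fn$omega_raw <- omega_raw
  idx_fs <- seq(1L, n_hr, by = res)
  t_fs <- t_hr[idx_fs]
  omega_fs <- omega_sm_hr[idx_fs]
  t_of <- function(i) t_hr[i]
  truth <- lapply(seq_len(n_cyc), function(c) {
    i_hs <- argmax_near(ev$hs[c], 1.5 * w_hs)
    i_to <- argmax_near(ev$to[c], 1.5 * w_to)
    seg <- i_hs:i_to
    at_below <- seg[abs(s[seg]) <= thr]
    below <- seg[abs(s[seg]) < thr]
    if (!length(at_below) || !length(below)) {
      fk_stop("flat-foot interval lost during template calibration",
              "parameter")
    }
    c(hs = i_hs, ts = at_below[1L], ho = below[length(below)] + 1L,
      to = i_to)
  })
  to_fs <- function(i_hr) as.integer(round(t_hr[i_hr] * p$fs)) + 1L
  rows <- lapply(seq_len(p$n_strides), function(k) {
    q <- truth[[k + 1L]]                       # cycle k (cycles 0-indexed)
    data.frame(stride = k, hs = to_fs(q[["hs"]]), ts = to_fs(q[["ts"]]),
               ho = to_fs(q[["ho"]]), to = to_fs(q[["to"]]),
               hs_next = to_fs(truth[[k + 2L]][["hs"]]))
  })
  events <- gait_events(do.call(rbind, rows), fs = p$fs, foot = "right")
  # truth phases from the high-resolution event times
  ph <- do.call(rbind, lapply(seq_len(p$n_strides), function(k) {
    q <- truth[[k + 1L]]; hsn <- truth[[k + 2L]][["hs"]]
    dur <- t_of(hsn) - t_of(q[["hs"]])
    data.frame(stride = k,
               lr = (t_of(q[["ts"]]) - t_of(q[["hs"]])) / dur * 100,
               ms = (t_of(q[["ho"]]) - t_of(q[["ts"]])) / dur * 100,
               ps = (t_of(q[["to"]]) - t_of(q[["ho"]])) / dur * 100,
               sw = (t_of(hsn) - t_of(q[["to"]])) / dur * 100)
  }))
  landmarks <- do.call(rbind, lapply(seq_len(p$n_strides), function(k) {
    kt <- z_knots_t(k + 1L)
    data.frame(stride = k,
               max1_mm = p$clearance_profile[["max1_mm"]],
               min_mm = p$clearance_profile[["min_mm"]],
               max2_mm = p$clearance_profile[["max2_mm"]],
               i_max1 = as.integer(round(kt[2L] * p$fs)) + 1L,
               i_min = as.integer(round(kt[3L] * p$fs)) + 1L,
               i_max2 = as.integer(round(kt[4L] * p$fs)) + 1L)
  }))

  structure(list(params = p, events = events, phases = ph,
                 sl_m = rep(SL, p$n_strides), landmarks = landmarks,
                 t = t_fs, pos = fn$pos(t_fs), vel = fn$vel(t_fs),
                 acc = fn$acc(t_fs), omega_dps = omega_fs,
                 theta_deg = theta_fun(t_fs), fn = fn,
                 # piecewise-polynomial joints: the trajectory is C2 but
                 # not C3 there, relevant to finite-difference checks
                 knots = sort(unique(c(z_segments$from, z_segments$to,
                                       x_spans$from, x_spans$to)))),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d stride(s) at %g Hz, ST %.3f s, SL %.2f m\n",
              x$params$n_strides, x$params$fs, x$params$stride_time_s,
              x$params$stride_length_m))
  invisible(x)
}

#' Simulate an IMU recording from a synthetic trajectory
#'
#' The sensor-frame specific force is the rotated sum of the true global
#' acceleration and gravity, plus a constant bias (applied to every axis)
#' and white noise; the gyroscope is the band-limited true angular
#' velocity plus white noise; the quaternions are the true sagittal-plane
#' (pitch-only) orientation. At zero noise and bias the full pipeline
#' applied to this recording recovers the ground truth within the
#' spatial-module tolerances.
#'
#' @param truth A [generate_trajectory()] result.
#' @param params Optional [gait_model_params()] overriding
#'   `truth$params` (e.g. different noise).
#' @param gravity Gravity constant, m/s^2.
#' @return An [imu_recording()].
#' @export
simulate_imu <- function(truth, params = truth$params, gravity = 9.80665) {
  stopifnot(inherits(truth, "gait_truth"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- length(truth$t)
  theta <- truth$theta_deg * pi / 180
  quat <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
  f_global <- truth$acc
  f_global[, 3L] <- f_global[, 3L] + gravity
  quat_conj <- cbind(quat[, 1L], -quat[, 2L], -quat[, 3L], -quat[, 4L])
  acc_sensor <- quat_rotate(quat_conj, f_global)
  acc_sensor <- acc_sensor + p$noise$accel_bias_mps2 +
    matrix(stats::rnorm(3L * n, sd = p$noise$accel_mps2), ncol = 3L)
  gyr <- cbind(stats::rnorm(n, sd = p$noise$gyro_dps),
               truth$omega_dps + stats::rnorm(n, sd = p$noise$gyro_dps),
               stats::rnorm(n, sd = p$noise$gyro_dps))
  imu_recording(t = truth$t, acc = acc_sensor, gyr = gyr, quat = quat,
                fs = p$fs, foot = "right")
}

#' Simulate a reference marker trajectory
#'
#' Marker positions are the true foot positions (converted to mm, plus a
#' constant lab-frame offset standing in for the marker's height above the
#' sensor origin) with white positional noise, on the same time base as
#' the IMU stream.
#'
#' @param truth A [generate_trajectory()] result.
#' @param marker_noise_mm White noise SD, mm.
#' @param offset_mm Constant lab-frame offset, mm.
#' @param seed Optional seed.
#' @return A [reference_trajectory()].
#' @export
simulate_markers <- function(truth, marker_noise_mm = 1,
                             offset_mm = c(0, 0, 80), seed = NULL) {
  stopifnot(inherits(truth, "gait_truth"))
  if (marker_noise_mm < 0) fk_stop("marker noise must be non-negative",
                                   "parameter")
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth$t)
  pos <- truth$pos * 1000
  pos <- sweep(pos, 2L, offset_mm, `+`)
  pos <- pos + matrix(stats::rnorm(3L * n, sd = marker_noise_mm), ncol = 3L)
  reference_trajectory(truth$t, pos, vertical_axis = "z")
}

#' Cohort specification for the synthetic study
#'
#' Per-group subject counts and subject-level parameter distributions
#' (mean and between-subject SD) for stride time, phase percentages,
#' stride length and clearance landmarks. Group means follow the
#' directionality reported in the clinical gait literature for Parkinson's
#' disease and freezing of gait: patients show longer midstance, shorter
#' loading response and swing, reduced stride length and reduced foot
#' elevation, with the freezing (FOG) subgroup most affected and
#' dopaminergic medication (on state) partially restoring performance.
#'
#' @param groups Optional data frame overriding the built-in group table
#'   (columns: `group`, `n`, `st`, `lr`, `ms`, `ps`, `sl`, `max1`, `min`,
#'   `max2`; `sw` is the remainder to 100).
#' @param sd Named list of between-subject SDs: `st`, `phase`, `sl`, `cl`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL,
                        sd = list(st = 0.08, phase = 1.5, sl = 0.15,
                                  cl = 12),
                        seed = 20260911L) {
  if (is.null(groups)) {
    groups <- data.frame(
      group = c("HC", "NOFOGoff", "NOFOGon", "FOGoff", "FOGon"),
      n = c(20L, 15L, 15L, 15L, 15L),
      st = c(1.05, 1.10, 1.05, 1.12, 1.00),
      lr = c(11.0, 10.0, 10.5, 9.0, 9.5),
      ms = c(40.0, 44.0, 42.0, 48.0, 45.0),
      ps = c(14.5, 14.0, 14.5, 13.5, 14.0),
      sl = c(1.30, 1.05, 1.15, 0.90, 1.00),
      max1 = c(150, 135, 140, 120, 128),
      min = c(90, 88, 89, 85, 87),
      max2 = c(120, 105, 112, 90, 98))
  }
  if (any(groups$n < 1L)) fk_stop("group counts must be >= 1", "parameter")
  sd <- utils::modifyList(list(st = 0.08, phase = 1.5, sl = 0.15, cl = 12),
                          as.list(sd))
  if (any(unlist(sd) < 0)) fk_stop("SDs must be non-negative", "parameter")
  structure(list(groups = groups, sd = sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one truncated-normal draw batch: redraw until predicate holds
draw_until <- function(n, gen, ok, max_tries = 1000L) {
  out <- gen(n)
  for (i in seq_len(max_tries)) {
    bad <- !ok(out)
    if (!any(bad)) return(out)
    out[bad] <- gen(sum(bad))[seq_len(sum(bad))]
  }
  fk_stop("could not draw valid cohort parameters", "parameter")
}

#' Generate a synthetic cohort
#'
#' Draws subject-level gait parameters from the group distributions of a
#' [cohort_spec()] and returns both a subject table (one row per subject,
#' including the pooled PDoff/PDon groups via [pool_pd_groups()] on the
#' long format) and the per-subject [gait_model_params()] needed to
#' simulate full IMU trials.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (data frame: `group`, `subject`, `st_s`,
#'   `lr`, `ms`, `ps`, `sw`, `sl_m`, `sp_mps`, `max1_mm`, `min_mm`,
#'   `max2_mm`, `gpqi`) and `params` (named list of
#'   [gait_model_params()]). GPQI is computed per subject against the
#'   healthy-control mean phase profile, using the subject's phases for
#'   both feet.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  sdv <- spec$sd
  rows <- list()
  for (i in seq_len(nrow(g))) {
    n <- g$n[i]
    st <- draw_until(n, function(m) stats::rnorm(m, g$st[i], sdv$st),
                     function(x) x > 0.85)
    lr <- draw_until(n, function(m) stats::rnorm(m, g$lr[i], sdv$phase),
                     function(x) x > 6)
    ms <- draw_until(n, function(m) stats::rnorm(m, g$ms[i], sdv$phase),
                     function(x) x > 10)
    ps <- draw_until(n, function(m) stats::rnorm(m, g$ps[i], sdv$phase),
                     function(x) x > 6)
    # realizability floor of the band-limited world: the rectified signal
    # cannot fall from its stance peak below the 30 deg/s threshold in
    # less than ~75 ms at a 3 Hz band limit, so loading-response and
    # pre-swing durations are floored there
    lr <- pmax(lr, 8 / st)
    ps <- pmax(ps, 8 / st)
    sw <- 100 - lr - ms - ps
    sl <- draw_until(n, function(m) stats::rnorm(m, g$sl[i], sdv$sl),
                     function(x) x > 0.2)
    max1 <- draw_until(n, function(m) stats::rnorm(m, g$max1[i], sdv$cl),
                       function(x) x > 20)
    min_ <- draw_until(n, function(m) stats::rnorm(m, g$min[i], sdv$cl),
                       function(x) x > 10)
    max2 <- draw_until(n, function(m) stats::rnorm(m, g$max2[i], sdv$cl),
                       function(x) x > 20)
    bad <- min_ > pmin(max1, max2) - 5 | sw < 15
    for (tries in seq_len(100L)) {
      if (!any(bad)) break
      k <- sum(bad)
      min_[bad] <- pmin(max1[bad], max2[bad]) - 5 - abs(stats::rnorm(k, 10, 5))
      sw[bad] <- pmax(sw[bad], 15)
      ms[bad] <- 100 - lr[bad] - ps[bad] - sw[bad]
      bad <- min_ > pmin(max1, max2) - 5 | min_ <= 10 | sw < 15
    }
    rows[[i]] <- data.frame(
      group = g$group[i], subject = sprintf("%s_%02d", g$group[i],
                                            seq_len(n)),
      st_s = st, lr = lr, ms = ms, ps = ps, sw = sw, sl_m = sl,
      sp_mps = sl / st, max1_mm = max1, min_mm = min_, max2_mm = max2)
  }
  subjects <- do.call(rbind, rows)
  hc <- subjects[subjects$group == "HC", ]
  ref <- reference_profile(data.frame(lr = hc$lr, ms = hc$ms, ps = hc$ps,
                                      sw = hc$sw))
  subjects$gpqi <- vapply(seq_len(nrow(subjects)), function(i) {
    pr <- subjects[i, c("lr", "ms", "ps", "sw")]
    pr <- unlist(pr) / sum(pr) * 100
    prof <- gait_phase_profile(pr[["lr"]], pr[["ms"]], pr[["ps"]],
                               pr[["sw"]])
    gpqi(prof, prof, ref)
  }, numeric(1L))
  params <- stats::setNames(lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    pf <- c(lr = s$lr, ms = s$ms, ps = s$ps, sw = s$sw) / 100
    # a shorter loading response / pre-swing means a sharper, stronger
    # angular-velocity pulse: scale the hump amplitudes so the band-limited
    # humps keep clearing the event threshold
    gait_model_params(stride_time_s = s$st_s, phase_fractions = pf,
                      stride_length_m = s$sl_m,
                      clearance_profile = c(max1_mm = s$max1_mm,
                                            min_mm = s$min_mm,
                                            max2_mm = s$max2_mm),
                      hs_peak_dps = min(400, 120 * 10.5 / s$lr),
                      to_peak_dps = min(450, 200 * 14.5 / s$ps),
                      seed = spec$seed + i)
  }), subjects$subject)
  list(subjects = subjects, params = params)
}

#' Long-format parameter table of a cohort
#'
#' Reshapes [generate_cohort()] subjects into the `group`, `parameter`,
#' `value` long format consumed by [run_comparison_grid()], with the
#' pooled PDoff/PDon groups appended.
#'
#' @param subjects The `subjects` data frame of [generate_cohort()].
#' @return Long-format data frame.
#' @export
cohort_long <- function(subjects) {
  pars <- c(ST = "st_s", LR = "lr", MS = "ms", PS = "ps", SW = "sw",
            SL = "sl_m", SP = "sp_mps", Max1 = "max1_mm", Min = "min_mm",
            Max2 = "max2_mm", GPQI = "gpqi")
  long <- do.call(rbind, lapply(names(pars), function(p) {
    data.frame(group = subjects$group, subject = subjects$subject,
               parameter = p, value = subjects[[pars[[p]]]])
  }))
  pool_pd_groups(long)
}
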