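# rotate sensor-frame vectors to the global frame with scalar-first
# Hamilton quaternions (sensor-to-global): v' = v + 2 q_v x (q_v x v + w v)
quat_rotate <- function(quat, v) {
  w <- quat[, 1L]; qx <- quat[, 2L]; qy <- quat[, 3L]; qz <- quat[, 4L]
  vx <- v[, 1L]; vy <- v[, 2L]; vz <- v[, 3L]
  tx <- qy * vz - qz * vy + w * vx
  ty <- qz * vx - qx * vz + w * vy
  tz <- qx * vy - qy * vx + w * vz
  cbind(vx + 2 * (qy * tz - qz * ty),
        vy + 2 * (qz * tx - qx * tz),
        vz + 2 * (qx * ty - qy * tx))
}

#' Rotate specific force to the global frame and remove gravity
#'
#' Rotates each sample's accelerometer reading into the global frame using
#' the orientation quaternion and subtracts the constant gravity vector
#' from the vertical (z) component. The result is the foot's linear
#' acceleration in the global frame, the quantity integrated by the ZUPT
#' dead-reckoning steps.
#'
#' @param rec An [imu_recording()] (accelerometer channels should already
#'   be low-pass filtered; see [extract_gait_metrics()]).
#' @param events Optional [gait_events()]; when given, the flat-foot
#'   intervals (toe strike to heel off of each stride) are attached for
#'   the ZUPT steps.
#' @param gravity Gravity constant, m/s^2.
#' @param acc Optional n x 3 matrix overriding `rec$acc` (e.g. the
#'   filtered accelerometer signal).
#' @return An object of class `global_accel`: list with `a_global`
#'   (n x 3, m/s^2), `flatfoot` (k x 2 matrix of sample intervals),
#'   `fs` and `n`.
#' @export
rotate_and_degravitate <- function(rec, events = NULL, gravity = 9.80665,
                                   acc = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(acc)) acc <- rec$acc
  qn <- sqrt(rowSums(rec$quat^2))
  if (any(abs(qn - 1) > 1e-6)) fk_stop("non-unit quaternion", "data")
  a_global <- quat_rotate(rec$quat, acc)
  a_global[, 3L] <- a_global[, 3L] - gravity
  ff <- if (is.null(events)) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("ts", "ho")))
  } else {
    flatfoot_intervals(events)
  }
  structure(list(a_global = a_global, flatfoot = ff,
                 fs = rec$fs, n = nrow(a_global)),
            class = "global_accel")
}

#' Flat-foot intervals of a stride sequence
#'
#' The flat-foot (midstance) interval of each stride runs from toe strike
#' to heel off; during it the foot is stationary and the ZUPT steps pin
#' the integrated velocity to zero.
#'
#' @param events A [gait_events()] object.
#' @return Integer matrix with columns `ts`, `ho`, ordered and
#'   non-overlapping.
#' @export
flatfoot_intervals <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  cbind(ts = events$ts, ho = events$ho)
}

# integrate one axis with zero-velocity updates: v = 0 on every flat-foot
# sample; between consecutive flat-foot intervals, cumulative trapezoidal
# integration anchored at v = 0, with a per-span linear detrend forcing
# the terminal velocity at the next flat-foot onset back to zero.
zupt_axis <- function(a, ff, fs, detrend = TRUE) {
  n <- length(a)
  v <- numeric(n)
  dt <- 1 / fs
  bounds <- rbind(c(NA_integer_, 1L),                # virtual start anchor
                  ff,
                  c(n, NA_integer_))                 # virtual end
  for (k in seq_len(nrow(bounds) - 1L)) {
    from <- bounds[k, 2L]                            # span start (anchored 0)
    to <- bounds[k + 1L, 1L]                         # span end
    if (is.na(from)) from <- 1L
    if (is.na(to)) to <- n
    if (to <= from) next
    idx <- from:to
    vv <- cumtrapz(a[idx], dt)
    anchored_end <- k < nrow(bounds) - 1L || !is.na(bounds[k + 1L, 2L])
    if (detrend && anchored_end && length(idx) > 1L) {
      vv <- vv - seq(0, 1, length.out = length(vv)) * vv[length(vv)]
    }
    v[idx] <- vv
  }
  for (k in seq_len(nrow(ff))) v[ff[k, 1L]:ff[k, 2L]] <- 0
  v
}

#' ZUPT-corrected velocity
#'
#' Integrates the global-frame acceleration into velocity with
#' zero-velocity updates: velocity is exactly zero on every flat-foot
#' sample; between consecutive flat-foot intervals the acceleration is
#' integrated with cumulative trapezoids starting from zero, and a linear
#' detrend over each span forces the terminal velocity at the next
#' flat-foot onset back to zero on each axis, cancelling drift from sensor
#' bias and integration error.
#'
#' @param ga A [rotate_and_degravitate()] result carrying flat-foot
#'   intervals.
#' @param fs Sampling rate, Hz (defaults to the rate stored in `ga`).
#' @param detrend Apply the per-span linear detrend (default `TRUE`;
#'   `FALSE` gives the uncorrected integration used to illustrate drift).
#' @return n x 3 velocity matrix, m/s.
#' @export
zupt_velocity <- function(ga, fs = ga$fs, detrend = TRUE) {
  stopifnot(inherits(ga, "global_accel"))
  if (!nrow(ga$flatfoot)) {
    fk_stop("no flat-foot intervals: ZUPT impossible", "zupt_impossible")
  }
  apply(ga$a_global, 2L, zupt_axis, ff = ga$flatfoot, fs = fs,
        detrend = detrend)
}

# horizontal displacement: |v_h| re-zeroed on flat foot, integrated per
# span (restarting from zero after each flat-foot interval)
horizontal_displacement <- function(v, ff, fs) {
  vh <- sqrt(v[, 1L]^2 + v[, 2L]^2)
  for (k in seq_len(nrow(ff))) vh[ff[k, 1L]:ff[k, 2L]] <- 0
  n <- length(vh)
  d <- numeric(n)
  starts <- c(1L, ff[, 2L])
  ends <- c(ff[, 1L], n)
  for (k in seq_along(starts)) {
    if (ends[k] <= starts[k]) next
    idx <- starts[k]:ends[k]
    d[idx] <- cumtrapz(vh[idx], 1 / fs)
  }
  for (k in seq_len(nrow(ff))) d[ff[k, 1L]:ff[k, 2L]] <- 0
  d
}

#' ZUPT stride length
#'
#' The horizontal velocity magnitude `vH = sqrt(vx^2 + vy^2)` is re-zeroed
#' on the flat-foot intervals and integrated per span into the horizontal
#' displacement `dH`; the stride length is the maximum of `dH` between two
#' successive heel strikes. Strides without flat-foot anchors on both
#' sides (first/last of a bout) are dropped and logged with `NA`.
#'
#' @param v n x 3 velocity from [zupt_velocity()].
#' @param ga The [rotate_and_degravitate()] result (for the flat-foot
#'   intervals).
#' @param events A [gait_events()] object.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of stride lengths in metres (one per stride,
#'   `NA` for dropped strides), with the displacement series as attribute
#'   `dH`.
#' @export
stride_length <- function(v, ga, events, fs = ga$fs) {
  stopifnot(inherits(ga, "global_accel"), inherits(events, "gait_events"))
  d <- horizontal_displacement(v, ga$flatfoot, fs)
  sl <- rep(NA_real_, nrow(events))
  for (k in seq_len(nrow(events))) {
    # anchored if a flat-foot interval both precedes the motion span and
    # follows the stride end (the next stride's toe strike)
    anchored <- any(ga$flatfoot[, 1L] <= events$ho[k]) &&
                any(ga$flatfoot[, 2L] >= events$hs_next[k])
    if (!anchored) next
    sl[k] <- max(d[events$hs[k]:(events$hs_next[k] - 1L)])
  }
  structure(sl, dH = d)
}

#' Naive double-integration stride length (drift baseline)
#'
#' Same displacement construction but with neither flat-foot re-zeroing
#' nor per-span detrending: velocity is one uncorrected cumulative
#' integral of acceleration. Under accelerometer bias this drifts and its
#' stride-length error exceeds the ZUPT-corrected error; it exists to
#' quantify what the ZUPT correction buys.
#'
#' @inheritParams stride_length
#' @return Numeric vector of stride lengths in metres.
#' @export
stride_length_naive <- function(ga, events, fs = ga$fs) {
  stopifnot(inherits(ga, "global_accel"), inherits(events, "gait_events"))
  v <- apply(ga$a_global, 2L, cumtrapz, dt = 1 / fs)
  vh <- sqrt(v[, 1L]^2 + v[, 2L]^2)
  d <- cumtrapz(vh, 1 / fs)
  vapply(seq_len(nrow(events)), function(k) {
    idx <- events$hs[k]:(events$hs_next[k] - 1L)
    max(d[idx]) - d[idx[1L]]
  }, numeric(1L))
}

#' Walking speed
#'
#' Stride length divided by the corresponding stride time.
#'
#' @param sl Stride length(s), m.
#' @param st Stride time(s), s.
#' @return Speed in m/s.
#' @export
speed <- function(sl, st) {
  if (any(!is.na(st) & st <= 0)) fk_stop("stride time must be positive",
                                         "data")
  sl / st
}

# landmark search on a clearance series within (from, to): Max1 = first
# local maximum, Max2 = last local maximum, Min = minimum between them.
# The prominence floor (mm) rejects spurious maxima raised by measurement
# noise on an otherwise smooth swing profile.
find_clearance_landmarks <- function(z, from, to, min_prominence_mm = 5) {
  out <- list(max1 = NA_real_, min = NA_real_, max2 = NA_real_,
              i_max1 = NA_integer_, i_min = NA_integer_,
              i_max2 = NA_integer_)
  if (to - from < 3L) return(out)
  idx <- (from + 1L):(to - 1L)                  # open interval
  seg <- z[idx]
  pk <- find_peaks(seg, min_distance = 1L,
                   min_prominence = min_prominence_mm)
  if (!length(pk)) return(out)
  out$i_max1 <- idx[pk[1L]]
  out$max1 <- z[out$i_max1]
  if (length(pk) >= 2L) {
    out$i_max2 <- idx[pk[length(pk)]]
    out$max2 <- z[out$i_max2]
    between <- out$i_max1:out$i_max2
    out$i_min <- between[which.min(z[between])]
    out$min <- z[out$i_min]
  }
  out
}

#' Foot clearance and its landmarks
#'
#' Foot clearance is the vertical displacement of the sensor relative to
#' the flat-foot baseline (defined as 0, since the absolute height of the
#' foot is unknown). The vertical axis of the ZUPT velocity is re-zeroed
#' on flat-foot intervals and integrated per span into a relative vertical
#' displacement; within each stride's swing interval (toe off to next heel
#' strike) the landmarks are the first local maximum (Max1), the last
#' local maximum (Max2) and the minimum between them (Min), reported in
#' millimetres. Strides whose swing holds fewer than two local maxima
#' retain a valid Max1 where present, with Min/Max2 flagged invalid.
#'
#' @param ga A [rotate_and_degravitate()] result with flat-foot intervals.
#' @param events A [gait_events()] object.
#' @param fs Sampling rate, Hz.
#' @param v Optional precomputed [zupt_velocity()] matrix.
#' @return Data frame with columns `stride`, `max1_mm`, `min_mm`,
#'   `max2_mm`, the landmark sample indices `i_max1`, `i_min`, `i_max2`,
#'   and logical validity flags `valid_max1`, `valid_min`, `valid_max2`;
#'   the full displacement series (mm) is attached as attribute
#'   `clearance_mm`.
#' @export
clearance <- function(ga, events, fs = ga$fs, v = NULL) {
  stopifnot(inherits(ga, "global_accel"), inherits(events, "gait_events"))
  if (is.null(v)) v <- zupt_velocity(ga, fs)
  vz <- v[, 3L]
  for (k in seq_len(nrow(ga$flatfoot))) {
    vz[ga$flatfoot[k, 1L]:ga$flatfoot[k, 2L]] <- 0
  }
  n <- length(vz)
  z <- numeric(n)
  starts <- c(1L, ga$flatfoot[, 2L])
  ends <- c(ga$flatfoot[, 1L], n)
  for (k in seq_along(starts)) {
    if (ends[k] <= starts[k]) next
    idx <- starts[k]:ends[k]
    z[idx] <- cumtrapz(vz[idx], 1 / fs)
  }
  for (k in seq_len(nrow(ga$flatfoot))) {
    z[ga$flatfoot[k, 1L]:ga$flatfoot[k, 2L]] <- 0
  }
  z_mm <- z * 1000
  res <- lapply(seq_len(nrow(events)), function(k) {
    lm <- find_clearance_landmarks(z_mm, events$to[k], events$hs_next[k])
    data.frame(stride = events$stride[k],
               max1_mm = lm$max1, min_mm = lm$min, max2_mm = lm$max2,
               i_max1 = lm$i_max1, i_min = lm$i_min, i_max2 = lm$i_max2,
               valid_max1 = !is.na(lm$max1),
               valid_min = !is.na(lm$min),
               valid_max2 = !is.na(lm$max2))
  })
  structure(do.call(rbind, res), clearance_mm = z_mm)
}
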