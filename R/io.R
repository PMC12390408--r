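#' Construct an IMU recording
#'
#' Container for one trial of synchronized foot-mounted IMU streams:
#' tri-axial specific force (accelerometer, m/s^2), tri-axial angular
#' velocity (gyroscope, deg/s) and the orientation quaternion per sample.
#' The quaternion is scalar-first (w, x, y, z), Hamilton convention, and
#' represents the sensor-to-global rotation: `v_global = R(q) %*% v_sensor`.
#'
#' @param t Time stamps in seconds, uniformly sampled, strictly increasing.
#' @param acc n x 3 matrix of specific force in the sensor frame, m/s^2.
#' @param gyr n x 3 matrix of angular velocity in the sensor frame, deg/s.
#'   Column 2 (the sensor y axis) is the sagittal channel used for gait
#'   event detection.
#' @param quat n x 4 matrix of unit quaternions (w, x, y, z).
#' @param fs Sampling rate in Hz; inferred from `t` when `NULL`.
#' @param foot `"left"` or `"right"` label.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyr, quat, fs = NULL, foot = "right") {
  t <- as.numeric(t)
  acc <- as_matrix3(acc, "acc")
  gyr <- as_matrix3(gyr, "gyr")
  quat <- as.matrix(quat)
  if (ncol(quat) != 4L) fk_stop("quat must have 4 columns (w, x, y, z)", "format")
  storage.mode(quat) <- "double"
  dimnames(quat) <- NULL
  n <- length(t)
  if (n < 2L) fk_stop("recording must contain at least 2 samples", "data")
  if (nrow(acc) != n || nrow(gyr) != n || nrow(quat) != n) {
    fk_stop("t, acc, gyr and quat must have equal lengths", "data")
  }
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    fk_stop("time must be finite and strictly increasing", "data")
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  if (!is.finite(fs) || fs <= 0) fk_stop("fs must be positive", "parameter")
  if (max(abs(diff(t) - 1 / fs)) > 1e-9) {
    fk_stop("time stamps are not uniform with step 1/fs (tolerance 1e-9)",
            "data")
  }
  qn <- sqrt(rowSums(quat^2))
  if (any(abs(qn - 1) > 1e-6)) {
    fk_stop(sprintf("%d quaternion(s) deviate from unit norm by more than 1e-6",
                    sum(abs(qn - 1) > 1e-6)), "data")
  }
  foot <- match.arg(foot, c("left", "right"))
  structure(list(t = t, acc = acc, gyr = gyr, quat = quat,
                 fs = fs, foot = foot),
            class = "imu_recording")
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) fk_stop(paste0(what, " must have 3 columns"), "format")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s foot, %d samples at %g Hz (%.2f s)\n",
              x$foot, length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

# canonical column roles of an IMU trial file
imu_roles <- function() {
  c(time = "t",
    acc_x = "ax", acc_y = "ay", acc_z = "az",
    gyr_x = "gx", gyr_y = "gy", gyr_z = "gz",
    quat_w = "qw", quat_x = "qx", quat_y = "qy", quat_z = "qz")
}

read_delimited <- function(path) {
  if (!file.exists(path)) fk_stop(paste0("file not found: ", path), "format")
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t"
         else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
}

#' Read one IMU trial from delimited text
#'
#' Accepts comma- or tab-delimited text with a header row. Column naming
#' varies between vendor exports, so a `column_map` translates file column
#' names to the roles the package needs: `time` (optional), `acc_x/y/z`,
#' `gyr_x/y/z`, `quat_w/x/y/z`. With the default map the expected names are
#' `t, ax, ay, az, gx, gy, gz, qw, qx, qy, qz`.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping roles to file column
#'   names, e.g. `c(time = "PacketTime", acc_x = "Acc_X", ...)`. Roles
#'   absent from the map fall back to the defaults.
#' @param fs Sampling rate in Hz; required when the file has no time
#'   column, otherwise inferred from the time stamps.
#' @param foot Foot label, `"left"` or `"right"`.
#' @return A validated [imu_recording()].
#' @export
load_imu_recording <- function(path, column_map = NULL, fs = NULL,
                               foot = "right") {
  map <- imu_roles()
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown)) {
      fk_stop(paste0("unknown column roles: ",
                     paste(unknown, collapse = ", ")), "format")
    }
    map[names(column_map)] <- column_map
  }
  df <- read_delimited(path)
  need <- setdiff(names(map), "time")
  missing <- need[!(map[need] %in% names(df))]
  if (length(missing)) {
    fk_stop(paste0("missing mandated column(s) for role(s): ",
                   paste(sprintf("%s (expected '%s')", missing, map[missing]),
                         collapse = ", ")), "format")
  }
  if (map[["time"]] %in% names(df)) {
    t <- df[[map[["time"]]]]
  } else {
    if (is.null(fs)) {
      fk_stop("file has no time column; supply fs explicitly", "parameter")
    }
    t <- (seq_len(nrow(df)) - 1L) / fs
  }
  imu_recording(
    t = t,
    acc = as.matrix(df[, map[c("acc_x", "acc_y", "acc_z")]]),
    gyr = as.matrix(df[, map[c("gyr_x", "gyr_y", "gyr_z")]]),
    quat = as.matrix(df[, map[c("quat_w", "quat_x", "quat_y", "quat_z")]]),
    fs = fs, foot = foot)
}

# write numeric columns at full double precision so read/write round-trips
write_numeric_table <- function(cols, path, sep = ",") {
  fmt <- vapply(cols, function(x) sprintf("%.17g", x), character(length(cols[[1L]])))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = 1L)
  lines <- c(paste(names(cols), collapse = sep),
             apply(fmt, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Write an IMU recording to delimited text
#'
#' Values are written at full double precision, so [load_imu_recording()]
#' recovers the numeric payload bit-identically.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @param sep Field separator, `","` or `"\t"`.
#' @return The path, invisibly.
#' @export
write_imu_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "imu_recording"))
  cols <- c(list(t = rec$t),
            stats::setNames(asplit(rec$acc, 2L), c("ax", "ay", "az")),
            stats::setNames(asplit(rec$gyr, 2L), c("gx", "gy", "gz")),
            stats::setNames(asplit(rec$quat, 2L), c("qw", "qx", "qy", "qz")))
  write_numeric_table(lapply(cols, as.numeric), path, sep)
}

#' Construct a reference marker trajectory
#'
#' Time-stamped 3-D marker positions in millimetres from an optoelectronic
#' (motion-capture) system, used as the reference in the clearance
#' agreement stage.
#'
#' @param t Time stamps, seconds, strictly increasing.
#' @param pos n x 3 matrix of marker positions, mm, lab frame.
#' @param vertical_axis Which column of `pos` is vertical: `"x"`, `"y"` or
#'   `"z"` (default).
#' @return An object of class `reference_trajectory`.
#' @export
reference_trajectory <- function(t, pos, vertical_axis = "z") {
  t <- as.numeric(t)
  pos <- as_matrix3(pos, "pos")
  if (length(t) != nrow(pos)) fk_stop("t and pos lengths differ", "data")
  if (any(!is.finite(pos))) fk_stop("non-finite marker coordinates", "data")
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    fk_stop("time must be finite and strictly increasing", "data")
  }
  vertical_axis <- match.arg(vertical_axis, c("x", "y", "z"))
  structure(list(t = t, pos = pos, vertical_axis = vertical_axis),
            class = "reference_trajectory")
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf("<reference_trajectory> %d samples (%.2f s), vertical axis %s\n",
              length(x$t), diff(range(x$t)), x$vertical_axis))
  invisible(x)
}

#' Read a reference marker trajectory from delimited text
#'
#' Expects columns `t, x, y, z` with time in seconds and positions in mm.
#'
#' @inheritParams load_imu_recording
#' @param vertical_axis Vertical component label (default `"z"`).
#' @return A validated [reference_trajectory()].
#' @export
load_reference_trajectory <- function(path, vertical_axis = "z") {
  df <- read_delimited(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df))) {
    fk_stop(paste0("missing mandated column(s): ",
                   paste(setdiff(need, names(df)), collapse = ", ")), "format")
  }
  reference_trajectory(df$t, as.matrix(df[, c("x", "y", "z")]),
                       vertical_axis = vertical_axis)
}

#' Write a reference trajectory to delimited text
#' @param traj A [reference_trajectory()].
#' @inheritParams write_imu_recording
#' @return The path, invisibly.
#' @export
write_reference_trajectory <- function(traj, path, sep = ",") {
  stopifnot(inherits(traj, "reference_trajectory"))
  write_numeric_table(list(t = traj$t, x = traj$pos[, 1L],
                           y = traj$pos[, 2L], z = traj$pos[, 3L]),
                      path, sep)
}
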