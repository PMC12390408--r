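#' Pipeline configuration
#'
#' Run configuration for the gait pipeline. Defaults follow the processing
#' settings of foot-worn gyroscope gait analysis: order-2 Butterworth
#' low-pass filters at 3 Hz (gyroscope) and 10 Hz (accelerometer), a
#' 30 deg/s threshold on the rectified sagittal angular velocity for the
#' toe-strike / heel-off crossings, and 10 central strides selected per
#' walking direction.
#'
#' @param gyro_cutoff_hz Gyroscope low-pass cutoff, Hz.
#' @param accel_cutoff_hz Accelerometer low-pass cutoff, Hz.
#' @param filter_order Butterworth design order (applied forward-backward,
#'   so the effective order doubles).
#' @param ts_ho_threshold_dps Threshold on |angular velocity|, deg/s,
#'   whose crossings define toe strike and heel off.
#' @param n_central_strides Strides retained per walking bout.
#' @param gravity_mps2 Gravity constant subtracted after rotation to the
#'   global frame, m/s^2.
#' @param gpqi_variant `"as_printed"` (sum of squared phase deviations over
#'   both feet) or `"per_foot_sqrt"` (sum over feet of per-foot Euclidean
#'   distances). See [gpqi()].
#' @param min_stride_s,max_stride_s Plausible stride duration band used
#'   when delimiting stride windows, seconds.
#' @param swing_prominence_dps Prominence floor for the dominant swing
#'   peak, deg/s.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gyro_cutoff_hz = 3,
                            accel_cutoff_hz = 10,
                            filter_order = 2L,
                            ts_ho_threshold_dps = 30,
                            n_central_strides = 10L,
                            gravity_mps2 = 9.80665,
                            gpqi_variant = c("as_printed", "per_foot_sqrt"),
                            min_stride_s = 0.4,
                            max_stride_s = 2.5,
                            swing_prominence_dps = 50,
                            seed = NULL) {
  gpqi_variant <- match.arg(gpqi_variant)
  cfg <- list(gyro_cutoff_hz = as.numeric(gyro_cutoff_hz),
              accel_cutoff_hz = as.numeric(accel_cutoff_hz),
              filter_order = as.integer(filter_order),
              ts_ho_threshold_dps = as.numeric(ts_ho_threshold_dps),
              n_central_strides = as.integer(n_central_strides),
              gravity_mps2 = as.numeric(gravity_mps2),
              gpqi_variant = gpqi_variant,
              min_stride_s = as.numeric(min_stride_s),
              max_stride_s = as.numeric(max_stride_s),
              swing_prominence_dps = as.numeric(swing_prominence_dps),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$gyro_cutoff_hz <= 0 || cfg$accel_cutoff_hz <= 0) {
    fk_stop("filter cutoffs must be positive", "parameter")
  }
  if (cfg$ts_ho_threshold_dps <= 0) {
    fk_stop("ts_ho_threshold_dps must be positive", "parameter")
  }
  if (cfg$n_central_strides < 1L) {
    fk_stop("n_central_strides must be >= 1", "parameter")
  }
  if (cfg$min_stride_s <= 0 || cfg$max_stride_s <= cfg$min_stride_s) {
    fk_stop("need 0 < min_stride_s < max_stride_s", "parameter")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    if (!is.null(x[[k]])) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  }
  invisible(x)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file is a plain-text subset of YAML: one `key: value` pair per line,
#' `#` comments allowed. Keys are the arguments of [pipeline_config()];
#' every default can be overridden.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) fk_stop(paste0("file not found: ", path), "format")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    fk_stop(paste0("cannot parse config line(s): ",
                   paste(lines[bad], collapse = "; ")), "format")
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    args[[keys[i]]] <- if (is.na(num)) v else num
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    fk_stop(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
            "format")
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to a flat key-value file
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keep <- !vapply(config, is.null, logical(1L))
  writeLines(sprintf("%s: %s", names(config)[keep],
                     vapply(config[keep], format, "")), path)
  invisible(path)
}
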