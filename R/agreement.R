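#' Normalize a reference marker trajectory to a clearance series
#'
#' The absolute marker height is arbitrary (it includes the marker's
#' standing height), so the optoelectronic clearance series is obtained by
#' subtracting the global minimum of the vertical component: the result is
#' non-negative with minimum exactly 0, matching the flat-foot baseline of
#' the IMU clearance.
#'
#' @param traj A [reference_trajectory()] or a numeric vector (mm).
#' @return Numeric clearance series, mm.
#' @export
normalize_reference <- function(traj) {
  z <- if (inherits(traj, "reference_trajectory")) {
    traj$pos[, match(traj$vertical_axis, c("x", "y", "z"))]
  } else {
    as.numeric(traj)
  }
  if (!length(z)) fk_stop("empty vertical component", "data")
  if (any(!is.finite(z))) fk_stop("non-finite vertical component", "data")
  z - min(z)
}

#' Pair clearance landmarks between IMU and reference systems
#'
#' For each stride, the landmark triple (Max1, Min, Max2) is extracted
#' from the reference clearance series over the same swing interval used
#' for the IMU (both systems share a synchronized time base), and paired
#' with the IMU landmarks. Strides with an invalid IMU or reference
#' landmark are excluded from that landmark's pairs and counted.
#'
#' @param imu_strides Data frame from [clearance()] (IMU landmarks with
#'   validity flags).
#' @param ref_clearance Reference clearance series, mm, from
#'   [normalize_reference()], on the same sample grid.
#' @param ref_events A [gait_events()] object delimiting the strides on
#'   the reference time base (typically the IMU events, since the streams
#'   are synchronized).
#' @return An object of class `landmark_pairs`: data frame with columns
#'   `stride`, `landmark` (`Max1`/`Min`/`Max2`), `x_os`, `x_imu` (mm);
#'   the number of excluded stride-landmark combinations is attribute
#'   `n_excluded`.
#' @export
pair_landmarks <- function(imu_strides, ref_clearance, ref_events) {
  stopifnot(inherits(ref_events, "gait_events"))
  if (nrow(imu_strides) != nrow(ref_events)) {
    a <- imu_strides$stride; b <- ref_events$stride
    fk_stop(paste0("stride-count mismatch after alignment; unmatched: ",
                   paste(union(setdiff(a, b), setdiff(b, a)),
                         collapse = ", ")), "alignment")
  }
  pairs <- list(); excluded <- 0L
  for (k in seq_len(nrow(ref_events))) {
    ref <- find_clearance_landmarks(ref_clearance, ref_events$to[k],
                                    ref_events$hs_next[k])
    imu <- imu_strides[k, ]
    for (lm in c("Max1", "Min", "Max2")) {
      key <- tolower(lm)
      x_os <- ref[[key]]
      x_imu <- imu[[paste0(key, "_mm")]]
      ok <- imu[[paste0("valid_", key)]] && !is.na(x_os)
      if (!ok) { excluded <- excluded + 1L; next }
      pairs[[length(pairs) + 1L]] <-
        data.frame(stride = imu$stride, landmark = lm,
                   x_os = x_os, x_imu = x_imu)
    }
  }
  if (!length(pairs)) fk_stop("no valid landmark pairs", "data")
  structure(do.call(rbind, pairs), n_excluded = excluded,
            class = c("landmark_pairs", "data.frame"))
}

#' Absolute and relative landmark errors
#'
#' Per pair, the absolute error `|x_os - x_imu|` (mm) and the absolute
#' relative percentage error `|x_os - x_imu| / |x_os| * 100`; the report
#' gives mean and standard deviation across pairs. Pairs with a zero
#' reference value are excluded from the relative error with a warning.
#'
#' @param pairs A data frame with columns `x_os`, `x_imu` (e.g. from
#'   [pair_landmarks()], possibly subset to one landmark).
#' @return List with `eabs_mean`, `eabs_sd` (mm), `erel_mean`, `erel_sd`
#'   (percent) and `n`.
#' @export
error_metrics <- function(pairs) {
  if (!nrow(pairs)) fk_stop("no pairs", "parameter")
  eabs <- abs(pairs$x_os - pairs$x_imu)
  nz <- pairs$x_os != 0
  if (any(!nz)) fk_warn(sprintf("%d pair(s) with zero reference excluded from relative error", sum(!nz)))
  erel <- eabs[nz] / abs(pairs$x_os[nz]) * 100
  list(eabs_mean = mean(eabs), eabs_sd = stats::sd(eabs),
       erel_mean = mean(erel), erel_sd = stats::sd(erel),
       n = nrow(pairs))
}

#' Bland-Altman agreement
#'
#' Signed differences `d = x_imu - x_os` (so a negative bias means the
#' IMU underestimates the reference), bias = mean(d) and 95% limits of
#' agreement `bias +/- 1.96 sd(d)` (sample SD, n - 1; the conventional
#' normal-quantile limits, not a t-based small-sample correction).
#'
#' @param pairs A data frame with columns `x_os`, `x_imu` (at least 2
#'   rows).
#' @return List with `bias`, `loa_low`, `loa_high` (mm), `sd` and `n`.
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 2L) fk_stop("Bland-Altman needs at least 2 pairs",
                                "parameter")
  d <- pairs$x_imu - pairs$x_os
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Full per-landmark agreement report
#'
#' Error metrics and Bland-Altman agreement for each landmark kind present
#' in the pairs.
#'
#' @param pairs A [pair_landmarks()] result.
#' @return Data frame with one row per landmark: `landmark`, `n`,
#'   `eabs_mean`, `eabs_sd`, `erel_mean`, `erel_sd`, `bias`, `loa_low`,
#'   `loa_high`.
#' @export
agreement_report <- function(pairs) {
  out <- lapply(split(as.data.frame(pairs), pairs$landmark), function(p) {
    em <- error_metrics(p)
    ba <- bland_altman(p)
    data.frame(landmark = p$landmark[1L], n = em$n,
               eabs_mean = em$eabs_mean, eabs_sd = em$eabs_sd,
               erel_mean = em$erel_mean, erel_sd = em$erel_sd,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$landmark, c("Max1", "Min", "Max2"))), ]
}

#' Bland-Altman plot
#'
#' Scatter of pair means against differences with bias and limits of
#' agreement as horizontal lines.
#'
#' @param pairs A data frame with `x_os`, `x_imu` columns.
#' @param main Plot title.
#' @return The [bland_altman()] summary, invisibly.
#' @export
plot_bland_altman <- function(pairs, main = "Bland-Altman") {
  ba <- bland_altman(pairs)
  m <- (pairs$x_imu + pairs$x_os) / 2
  d <- pairs$x_imu - pairs$x_os
  graphics::plot(m, d, xlab = "Mean of methods (mm)",
                 ylab = "IMU - reference (mm)", main = main, pch = 19)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}
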