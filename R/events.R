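# local maxima of x with prominence and minimum-distance constraints.
# Returns sorted sample indices. Plateaus take the first plateau sample.
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # strictly-rising then non-rising turns; skip flat runs by carrying sign
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_filled <- s
  last <- 0
  for (i in seq_len(n - 1L)) {       # fill plateau signs with previous slope
    if (s_filled[i] == 0) s_filled[i] <- last else last <- s_filled[i]
  }
  cand <- which(s_filled[-(n - 1L)] > 0 & s_filled[-1L] < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1L))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # greedy minimum-distance enforcement, highest peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_distance)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

peak_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i > 1L) {
    j <- i - 1L
    lo <- x[i]
    while (j >= 1L && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j - 1L }
    lo
  } else x[i]
  right <- if (i < n) {
    j <- i + 1L
    lo <- x[i]
    while (j <= n && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j + 1L }
    lo
  } else x[i]
  x[i] - max(left, right)
}

# Decide the channel sign so that the two stance-adjacent extrema (toe off,
# heel strike) are maxima: the dominant per-cycle extremum (mid-swing) must
# then be negative. Returns +1 (keep) or -1 (flip).
sagittal_sign <- function(omega, fs, min_stride_s, prominence) {
  dist <- max(1L, floor(min_stride_s * fs))
  # height floor alongside prominence: the flat-foot plateau between the
  # two stance humps forms spurious low peaks of the opposite sign
  pos <- find_peaks(omega, dist, prominence)
  pos <- pos[omega[pos] >= prominence]
  neg <- find_peaks(-omega, dist, prominence)
  neg <- neg[-omega[neg] >= prominence]
  hi_pos <- if (length(pos)) stats::median(omega[pos]) else -Inf
  hi_neg <- if (length(neg)) stats::median(-omega[neg]) else -Inf
  if (hi_pos == -Inf && hi_neg == -Inf) {
    fk_stop("no dominant peaks found in sagittal angular velocity",
            "no_strides")
  }
  if (hi_pos >= hi_neg) -1 else 1
}

#' Delimit stride windows from the sagittal angular velocity
#'
#' Stride cycles are delimited by consecutive dominant swing peaks of the
#' filtered sagittal angular-velocity signal: the mid-swing extremum is the
#' most robust per-cycle landmark in foot-worn gyroscope data. The channel
#' sign is auto-oriented so that the stance-adjacent extrema (heel strike
#' and toe off) are maxima; mounting differences between feet and devices
#' flip the raw sign.
#'
#' @param omega_sag Filtered sagittal angular velocity, deg/s.
#' @param fs Sampling rate, Hz.
#' @param min_stride_s,max_stride_s Admissible stride duration band,
#'   seconds; windows outside the band are discarded.
#' @param prominence_dps Prominence floor for the dominant swing peak,
#'   deg/s.
#' @return An object of class `stride_windows`: a data frame with columns
#'   `start`, `end` (sample indices), carrying the orientation sign as
#'   attribute `sign`.
#' @export
find_stride_windows <- function(omega_sag, fs, min_stride_s = 0.4,
                                max_stride_s = 2.5, prominence_dps = 50) {
  sgn <- sagittal_sign(omega_sag, fs, min_stride_s, prominence_dps)
  s <- sgn * omega_sag
  dist <- max(1L, floor(min_stride_s * fs))
  troughs <- find_peaks(-s, dist, prominence_dps)
  troughs <- troughs[-s[troughs] >= prominence_dps]
  if (length(troughs) < 2L) {
    fk_stop("fewer than 2 dominant swing peaks: no strides found",
            "no_strides")
  }
  start <- troughs[-length(troughs)]
  end <- troughs[-1L]
  dur <- (end - start) / fs
  ok <- dur >= min_stride_s & dur <= max_stride_s
  if (!any(ok)) {
    fk_stop("no stride window within the admissible duration band",
            "no_strides")
  }
  structure(data.frame(start = start[ok], end = end[ok]),
            sign = sgn, class = c("stride_windows", "data.frame"))
}

#' Detect gait events within stride windows
#'
#' Within each stride window the two most prominent local maxima of the
#' oriented sagittal signal are the stance-adjacent extrema; the earlier is
#' heel strike (HS), the later toe off (TO) - temporally HS always
#' precedes TO between consecutive swing peaks, and the TO (push-off) peak
#' is the larger of the two. Toe strike (TS) is the first sample after HS
#' where the rectified signal falls below the threshold; heel off (HO) is
#' the last sample before TO where it rises back above the threshold, so
#' TS and HO bracket the flat-foot interval. A stride is emitted only when
#' a full quadruple plus the next HS is found and the ordering
#' `hs < ts < ho < to < hs_next` holds; failing strides are dropped and
#' logged, never repaired.
#'
#' @param omega_sag Filtered sagittal angular velocity, deg/s (same signal
#'   passed to [find_stride_windows()]).
#' @param windows A `stride_windows` object.
#' @param threshold_dps Crossing threshold on |angular velocity|, deg/s.
#' @param fs Sampling rate, Hz.
#' @param foot Foot label.
#' @return An object of class `gait_events`: a data frame with one row per
#'   stride and columns `stride`, `hs`, `ts`, `ho`, `to`, `hs_next`
#'   (sample indices), with attributes `fs`, `foot` and `dropped` (a data
#'   frame of dropped windows and reasons).
#' @export
detect_events <- function(omega_sag, windows, threshold_dps = 30,
                          fs = attr(windows, "fs"), foot = "right") {
  stopifnot(inherits(windows, "stride_windows"))
  if (threshold_dps <= 0) fk_stop("threshold must be positive", "parameter")
  s <- attr(windows, "sign") * omega_sag
  quads <- vector("list", nrow(windows))
  dropped <- list()
  for (w in seq_len(nrow(windows))) {
    a <- windows$start[w]; b <- windows$end[w]
    seg <- s[a:b]
    pk <- find_peaks(seg, min_distance = 1L, min_prominence = threshold_dps / 2)
    pk <- pk[seg[pk] > threshold_dps]
    if (length(pk) < 2L) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(window = w, reason = "fewer than two local maxima")
      next
    }
    prom <- vapply(pk, function(i) peak_prominence(seg, i), numeric(1L))
    two <- sort(pk[order(prom, decreasing = TRUE)[1:2]])
    hs <- a + two[1L] - 1L
    to <- a + two[2L] - 1L
    # TS: first sample at or below the threshold after HS (the downward
    # crossing sample); HO: first sample back at or above it before TO.
    at_below <- which(abs(s[hs:to]) <= threshold_dps)
    if (!length(at_below)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(window = w, reason = "no flat foot: |omega| never below threshold")
      next
    }
    ts <- hs + at_below[1L] - 1L
    strictly_below <- which(abs(s[hs:to]) < threshold_dps)
    last_below <- if (length(strictly_below)) max(strictly_below) else at_below[length(at_below)]
    ho <- hs + last_below - 1L + 1L
    if (!(hs < ts && ts < ho && ho < to)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(window = w, reason = "event ordering violated")
      next
    }
    quads[[w]] <- c(hs = hs, ts = ts, ho = ho, to = to)
  }
  ev <- list(); k <- 0L
  for (w in seq_len(max(0L, length(quads) - 1L))) {
    q <- quads[[w]]
    if (is.null(q) || is.null(quads[[w + 1L]])) next
    # a stride needs temporally adjacent windows (no skipped cycle between)
    if (windows$end[w] != windows$start[w + 1L]) next
    nxt <- quads[[w + 1L]][["hs"]]
    if (q[["to"]] >= nxt) next
    k <- k + 1L
    ev[[k]] <- data.frame(stride = k, hs = q[["hs"]], ts = q[["ts"]],
                          ho = q[["ho"]], to = q[["to"]], hs_next = nxt)
  }
  if (!k) fk_stop("no complete stride detected", "no_strides")
  out <- do.call(rbind, ev)
  gait_events(out, fs = fs, foot = foot,
              dropped = if (length(dropped)) do.call(rbind, dropped)
                        else data.frame(window = integer(0),
                                        reason = character(0)))
}

#' Construct / validate a gait-events table
#'
#' @param df Data frame with columns `stride`, `hs`, `ts`, `ho`, `to`,
#'   `hs_next` (sample indices).
#' @param fs Sampling rate, Hz.
#' @param foot Foot label.
#' @param dropped Optional data frame logging dropped strides.
#' @return The validated `gait_events` object.
#' @export
gait_events <- function(df, fs, foot = "right", dropped = NULL) {
  need <- c("stride", "hs", "ts", "ho", "to", "hs_next")
  if (!all(need %in% names(df))) {
    fk_stop(paste0("gait events need columns: ", paste(need, collapse = ", ")),
            "format")
  }
  df <- as.data.frame(df)[, need]
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    fk_stop("fs must be positive", "parameter")
  }
  ok <- with(df, hs < ts & ts < ho & ho < to & to < hs_next)
  if (any(!ok)) fk_stop("event ordering hs<ts<ho<to<hs_next violated", "data")
  if (nrow(df) > 1L) {
    if (any(diff(df$hs) <= 0) || any(df$hs_next[-nrow(df)] > df$hs[-1L])) {
      fk_stop("strides must be ordered and non-overlapping", "data")
    }
  }
  structure(df, fs = fs, foot = foot,
            dropped = dropped, class = c("gait_events", "data.frame"))
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s foot, %d stride(s) at %g Hz",
              attr(x, "foot"), nrow(x), attr(x, "fs")))
  dr <- attr(x, "dropped")
  if (!is.null(dr) && nrow(dr)) cat(sprintf(", %d window(s) dropped", nrow(dr)))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Select the central strides of each walking bout
#'
#' Strides at the start and end of a walking bout are contaminated by
#' acceleration, deceleration and turning, so only the central strides of
#' each straight-walk bout are analyzed (by default 10 per direction, 20
#' per out-and-back trial). Bout boundaries are an explicit input; turning
#' detection is out of scope.
#'
#' @param events A [gait_events()] object.
#' @param segments List of `c(start, end)` sample-index pairs, one per
#'   walking bout.
#' @param n_per_segment Number of strides to keep per bout. If a bout holds
#'   fewer, all are retained with a warning.
#' @return A [gait_events()] object restricted to the selected strides
#'   (stride indices renumbered).
#' @export
select_central_strides <- function(events, segments, n_per_segment = 10L) {
  stopifnot(inherits(events, "gait_events"))
  if (!length(segments)) fk_stop("empty segment list", "parameter")
  keep <- integer(0)
  for (seg in segments) {
    if (length(seg) != 2L || seg[2L] <= seg[1L]) {
      fk_stop("each segment must be c(start, end) with start < end",
              "parameter")
    }
    inside <- which(events$hs >= seg[1L] & events$hs_next <= seg[2L])
    if (!length(inside)) next
    if (length(inside) < n_per_segment) {
      fk_warn(sprintf("segment [%g, %g] holds %d strides (< %d); keeping all",
                      seg[1L], seg[2L], length(inside), n_per_segment))
      sel <- inside
    } else {
      mid <- mean(seg)
      d <- abs((events$hs[inside] + events$hs_next[inside]) / 2 - mid)
      sel <- inside[order(d)][seq_len(n_per_segment)]
    }
    keep <- c(keep, sort(sel))
  }
  if (!length(keep)) fk_stop("no strides inside the given segments",
                             "no_strides")
  out <- events[keep, , drop = FALSE]
  out$stride <- seq_len(nrow(out))
  gait_events(out, fs = attr(events, "fs"), foot = attr(events, "foot"),
              dropped = attr(events, "dropped"))
}

#' Export gait events as delimited text
#' @param events A [gait_events()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gait_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- cbind(foot = attr(events, "foot"), as.data.frame(events))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
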