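#' Stride time
#'
#' Stride time (ST) is the time elapsed between two consecutive heel
#' strikes of the same foot.
#'
#' @param events A [gait_events()] object.
#' @return Numeric vector of stride times in seconds, one per stride.
#' @export
stride_time <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  (events$hs_next - events$hs) / attr(events, "fs")
}

#' Construct a gait-phase profile
#'
#' The four-phase stride model: loading response (LR, heel strike to toe
#' strike), midstance (MS, the flat-foot period from toe strike to heel
#' off), pre-swing (PS, heel off to toe off) and swing (SW, toe off to the
#' next heel strike), each expressed as a percentage of stride time. The
#' four percentages must sum to 100.
#'
#' @param lr,ms,ps,sw Phase percentages (each in `[0, 100]`).
#' @return An object of class `gait_phase_profile` (a named numeric
#'   vector).
#' @export
gait_phase_profile <- function(lr, ms, ps, sw) {
  p <- c(lr = as.numeric(lr), ms = as.numeric(ms),
         ps = as.numeric(ps), sw = as.numeric(sw))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    fk_stop("phase percentages must be finite and within [0, 100]", "data")
  }
  if (abs(sum(p) - 100) > 1e-9) {
    fk_stop(sprintf("phase percentages sum to %.12g, not 100", sum(p)),
            "data")
  }
  structure(p, class = "gait_phase_profile")
}

#' @export
print.gait_phase_profile <- function(x, ...) {
  cat(sprintf("<gait_phase_profile> LR %.2f%% | MS %.2f%% | PS %.2f%% | SW %.2f%%\n",
              x[["lr"]], x[["ms"]], x[["ps"]], x[["sw"]]))
  invisible(x)
}

#' Gait-phase percentages per stride
#'
#' Converts event indices into the four-phase percentages of stride time:
#' `phase% = t(phase) / ST * 100`.
#'
#' @param events A [gait_events()] object.
#' @return Data frame with columns `stride`, `lr`, `ms`, `ps`, `sw`
#'   (percentages, each row summing to 100).
#' @export
gait_phases <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  dur <- events$hs_next - events$hs
  if (any(dur <= 0)) fk_stop("zero-length stride", "data")
  data.frame(stride = events$stride,
             lr = (events$ts - events$hs) / dur * 100,
             ms = (events$ho - events$ts) / dur * 100,
             ps = (events$to - events$ho) / dur * 100,
             sw = (events$hs_next - events$to) / dur * 100)
}

#' Cadence
#'
#' Number of strides divided by the total gait duration in minutes,
#' rounded down to the nearest integer. The duration of the analyzed walk
#' should span from the first to the last heel strike of the selected
#' strides (see [gait_duration()]).
#'
#' @param events A [gait_events()] object, or an integer stride count.
#' @param duration_s Total gait duration in seconds.
#' @return Integer cadence in strides per minute.
#' @export
cadence <- function(events, duration_s) {
  n <- if (inherits(events, "gait_events")) nrow(events) else as.numeric(events)
  if (!is.finite(duration_s) || duration_s <= 0) {
    fk_stop("duration_s must be positive", "parameter")
  }
  as.integer(floor(n / (duration_s / 60)))
}

#' Gait duration of the analyzed strides
#'
#' Span from the first heel strike to the last heel strike of the analyzed
#' strides. Central-stride selection removes the acceleration and
#' deceleration at the ends of the walk, so the duration must match the
#' counted strides rather than the raw trial length.
#'
#' @param events A [gait_events()] object.
#' @return Duration in seconds.
#' @export
gait_duration <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  (max(events$hs_next) - min(events$hs)) / attr(events, "fs")
}

as_phase_vec <- function(p) {
  if (inherits(p, "gait_phase_profile")) return(unclass(p))
  if (is.data.frame(p)) p <- unlist(p[1L, c("lr", "ms", "ps", "sw")])
  p <- p[c("lr", "ms", "ps", "sw")]
  if (any(is.na(p))) fk_stop("need named phases lr, ms, ps, sw", "format")
  p
}

#' Gait Phase Quality Index (GPQI)
#'
#' Scalar discrepancy between a subject's gait-phase distribution (both
#' feet) and a reference distribution obtained from healthy subjects.
#' A lower GPQI indicates a phase distribution closer to the reference and
#' therefore higher gait quality.
#'
#' Two readings of the index are supported, because the radical placement
#' in the printed formula of the originating literature is typographically
#' ambiguous:
#' \describe{
#'   \item{`as_printed`}{the sum over both feet of the summed squared
#'     phase deviations (no square root): `sum_f sum_p (p_sub - p_ref)^2`.}
#'   \item{`per_foot_sqrt`}{the sum over feet of the per-foot Euclidean
#'     distance: `sum_f sqrt(sum_p (p_sub - p_ref)^2)`.}
#' }
#'
#' @param subject_left,subject_right [gait_phase_profile()]s (or named
#'   vectors with `lr`, `ms`, `ps`, `sw`) for the two feet.
#' @param reference Reference profile (see [reference_profile()]).
#' @param variant `"as_printed"` (default) or `"per_foot_sqrt"`.
#' @return Non-negative scalar; 0 iff both feet match the reference
#'   exactly.
#' @export
gpqi <- function(subject_left, subject_right, reference,
                 variant = c("as_printed", "per_foot_sqrt")) {
  variant <- match.arg(variant)
  ref <- as_phase_vec(reference)
  d2 <- vapply(list(as_phase_vec(subject_left), as_phase_vec(subject_right)),
               function(p) sum((p - ref)^2), numeric(1L))
  switch(variant,
         as_printed = sum(d2),
         per_foot_sqrt = sum(sqrt(d2)))
}

#' Reference gait-phase profile from a control cohort
#'
#' Componentwise mean of the supplied profiles, renormalized to sum to
#' exactly 100.
#'
#' @param profiles A data frame with columns `lr`, `ms`, `ps`, `sw` (one
#'   row per subject or stride) or a list of [gait_phase_profile()]s.
#' @return A [gait_phase_profile()].
#' @export
reference_profile <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (!nrow(profiles)) fk_stop("empty profile collection", "parameter")
    m <- colMeans(profiles[, c("lr", "ms", "ps", "sw")])
  } else {
    if (!length(profiles)) fk_stop("empty profile collection", "parameter")
    m <- rowMeans(vapply(profiles, as_phase_vec, numeric(4L)))
  }
  m <- m / sum(m) * 100
  gait_phase_profile(m[["lr"]], m[["ms"]], m[["ps"]], m[["sw"]])
}
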