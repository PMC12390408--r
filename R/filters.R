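#' Low-pass Butterworth coefficients
#'
#' Designs a digital low-pass Butterworth filter by the standard analog
#' prototype / bilinear transform route with frequency pre-warping, and
#' returns the transfer-function coefficients normalized so that `a[1] = 1`
#' and the DC gain is exactly 1.
#'
#' @param cutoff Cutoff frequency in Hz (-3 dB point). Must be below the
#'   Nyquist frequency `fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (number of analog poles).
#' @return A list with numerator `b` and denominator `a` coefficient
#'   vectors, each of length `order + 1`.
#' @seealso [butterworth_lowpass()] for zero-phase filtering of a signal.
#' @export
butter_lowpass <- function(cutoff, fs, order = 2L) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.numeric(fs),
            length(fs) == 1L, fs > 0, order >= 1L)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    fk_stop(sprintf("cutoff %g Hz must lie in (0, fs/2) = (0, %g) Hz",
                    cutoff, fs / 2), "parameter")
  }
  order <- as.integer(order)
  wc <- tan(pi * cutoff / fs)                  # pre-warped analog cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  s <- wc * complex(real = cos(theta), imaginary = sin(theta))
  z <- (1 + s) / (1 - s)                       # bilinear transform of poles
  a <- Re(poly_from_roots(z))
  b <- poly_from_roots(rep(-1 + 0i, order))    # order zeros at z = -1
  b <- Re(b) * sum(a) / sum(Re(b))             # unity DC gain
  list(b = b, a = a)
}

# expand prod_k (x - r_k) into coefficient vector (highest power first)
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (rk in r) coefs <- c(coefs, 0) - c(0, coefs * rk)
  coefs
}

# single-pass direct-form IIR filter, zero initial conditions
iir_filter <- function(b, a, x) {
  nb <- length(b)
  # moving-average part via C-level convolution filter
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies the low-pass Butterworth filter of [butter_lowpass()] forward and
#' backward (zero-phase filtering), so that no phase lag is introduced into
#' the signal. Event timing read off the filtered signal is therefore not
#' biased by the filter. Note the forward-backward pass squares the
#' magnitude response: an order-2 design has an effective order of 4.
#'
#' Edge transients are controlled by odd-reflection padding at both ends;
#' the padding is long enough for the filter transient to decay below 1e-4.
#'
#' @param x Numeric vector, uniformly sampled signal.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Design order of the underlying one-pass filter (default 2).
#' @param fs Sampling rate, Hz.
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' x <- sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t)
#' y <- butterworth_lowpass(x, cutoff = 10, order = 2, fs = 100)
#' @export
butterworth_lowpass <- function(x, cutoff, order = 2L, fs) {
  coef <- butter_lowpass(cutoff, fs, order)
  n <- length(x)
  pad <- min(n - 1L, max(3L * (2L * order + 1L), ceiling(2 * fs / cutoff)))
  if (pad < 1L) fk_stop("signal too short to filter", "parameter")
  x_ext <- c(2 * x[1L] - x[(pad + 1L):2L],
             x,
             2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter(coef$b, coef$a, x_ext)
  y <- rev(iir_filter(coef$b, coef$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Cumulative trapezoidal integration
#'
#' Integrates a uniformly sampled series with the trapezoid rule,
#' starting at 0. This is the integration scheme used by every
#' dead-reckoning step in the package.
#'
#' @param y Numeric vector.
#' @param dt Sample spacing (1/fs).
#' @return Numeric vector of the same length; first element 0.
#' @export
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dt
}
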