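# Zero-lag Butterworth low-pass filtering.
#
# No IIR filtering routines ship with base R, so the standard digital
# Butterworth design (analog prototype poles -> bilinear transform) and a
# forward-backward pass with steady-state initial conditions are implemented
# here. The "fourth-order zero-lag" filter conventional in biomechanics is
# realised as a dual pass of a second-order design (effective order 4).

# Polynomial coefficients (descending powers) from roots, real part taken.
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Digital Butterworth low-pass design
#'
#' Bilinear-transform design of an order-`n` Butterworth low pass with cutoff
#' `cutoff` Hz at sampling rate `rate` Hz (cutoff pre-warped).
#'
#' @param order filter order (>= 1).
#' @param cutoff -3 dB cutoff frequency, Hz; must be below `rate/2`.
#' @param rate sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (descending powers of z^-1, `a[1] == 1`).
#' @export
butter_lowpass <- function(order, cutoff, rate) {
  if (order < 1L) jw_abort("order must be >= 1", "jw_argument_error")
  if (cutoff <= 0 || cutoff >= rate / 2) {
    jw_abort("cutoff must lie in (0, rate/2)", "jw_argument_error")
  }
  wc <- 2 * rate * tan(pi * cutoff / rate)     # pre-warped analog cutoff (rad/s)
  k <- seq_len(order)
  pa <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left-half-plane poles
  fs2 <- 2 * rate
  pz <- (fs2 + pa) / (fs2 - pa)                # bilinear transform
  a <- poly_from_roots(pz)
  b <- poly_from_roots(rep(-1 + 0i, order))    # zeros at z = -1
  b <- b * sum(a) / sum(b)                     # unit DC gain
  list(b = b, a = a)
}

# Direct-form-II-transposed IIR filter with optional initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(a)
  if (length(b) != n) jw_abort("b and a must have equal length", "jw_argument_error")
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (n > 2L) {
      for (j in seq_len(n - 2L)) {
        z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
      }
    }
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state (unit step) initial filter state, as in scipy.signal.lfilter_zi.
iir_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  A[, 1L] <- A[, 1L] - a[-1L]          # companion(a)^T
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n) - A, B)
}

# Forward-backward filtering with odd-reflection padding.
filtfilt_jw <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3L * (length(a) - 1L)
  padlen <- min(n - 1L, padlen)
  if (padlen < 1L) jw_abort("series too short to filter", "jw_argument_error")
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1L])
  y <- rev(y)
  y[seq(padlen + 1L, padlen + n)]
}

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward ("zero phase shift") Butterworth low-pass filtering of
#' every channel of a time series. `order` is the effective order: following
#' the convention for zero-lag filters in movement analysis, an effective
#' order-4 filter is a dual pass of an order-2 design. Output length, rate and
#' time grid are unchanged.
#'
#' @param series a [timeseries()] object.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order effective filter order; even (each pass uses `order/2`).
#' @return Filtered [timeseries()].
#' @export
lowpass_zero_lag <- function(series, cutoff, order = 4L) {
  validate_timeseries(series)
  if (cutoff >= series$rate / 2) {
    jw_abort("cutoff must be below the Nyquist frequency", "jw_argument_error")
  }
  if (order %% 2L != 0L || order < 2L) {
    jw_abort("order must be a positive even number (effective order of the dual pass)",
             "jw_argument_error")
  }
  dsg <- butter_lowpass(order %/% 2L, cutoff, series$rate)
  # pad generously: zero-lag transients scale with rate/cutoff, not filter length
  padlen <- max(3L * (length(dsg$a) - 1L), ceiling(3 * series$rate / cutoff))
  out <- series
  for (j in seq_len(ncol(series$values))) {
    out$values[, j] <- filtfilt_jw(dsg$b, dsg$a, series$values[, j], padlen = padlen)
  }
  out
}
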