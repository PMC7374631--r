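#' Uniformly sampled multichannel time series
#'
#' The basic signal container used throughout the package: a uniform time grid
#' `t` (seconds, origin at recording start), a numeric matrix of channel values
#' (one column per channel), the nominal sampling rate in Hz and a unit string.
#'
#' @param values numeric vector or matrix (rows = samples, columns = channels).
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param units unit label carried along for bookkeeping.
#' @param channels optional channel names (defaults to existing colnames).
#' @return An object of class `jw_ts` with fields `t`, `values`, `rate`, `units`.
#' @export
timeseries <- function(values, rate, t0 = 0, units = "", channels = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    jw_abort("rate must be a single positive number", "jw_argument_error")
  }
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  if (nrow(v) < 1L) jw_abort("time series must contain at least one sample", "jw_argument_error")
  if (!is.null(channels)) colnames(v) <- channels
  ts <- structure(
    list(t = t0 + (seq_len(nrow(v)) - 1) / rate, values = v, rate = rate, units = units),
    class = "jw_ts"
  )
  ts
}

ts_n <- function(ts) nrow(ts$values)

ts_channel <- function(ts, name) {
  if (!name %in% colnames(ts$values)) {
    jw_abort(sprintf("missing channel '%s'", name), "jw_format_error")
  }
  ts$values[, name]
}

#' Validate a time series against its invariants
#'
#' Checks equal lengths, strictly increasing time, and uniform spacing equal to
#' `1/rate` within 1e-9 s.
#'
#' @param ts a [timeseries()] object.
#' @param allow_na allow missing values (used by ground-truth channels that are
#'   undefined during flight).
#' @return `ts`, invisibly; aborts with class `jw_format_error` otherwise.
#' @export
validate_timeseries <- function(ts, allow_na = FALSE) {
  if (!inherits(ts, "jw_ts")) jw_abort("not a jw_ts object", "jw_format_error")
  if (length(ts$t) != nrow(ts$values)) {
    jw_abort("time vector and value rows differ in length", "jw_format_error")
  }
  dt <- diff(ts$t)
  if (length(dt) && any(dt <= 0)) {
    jw_abort("time vector is not strictly increasing", "jw_format_error")
  }
  if (length(dt) && max(abs(dt - 1 / ts$rate)) > 1e-9) {
    jw_abort(sprintf("sample spacing deviates from 1/%g Hz by more than 1e-9 s", ts$rate),
             "jw_format_error")
  }
  if (!allow_na && !all(is.finite(ts$values))) {
    idx <- which(!is.finite(ts$values), arr.ind = TRUE)[1L, ]
    jw_abort(sprintf("non-finite value at sample %d, channel %d", idx[1L], idx[2L]),
             "jw_format_error")
  }
  invisible(ts)
}

#' @export
print.jw_ts <- function(x, ...) {
  cat(sprintf("<jw_ts> %d samples x %d channels @ %g Hz [%s], t = %.4f..%.4f s\n",
              nrow(x$values), ncol(x$values), x$rate,
              x$units, x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' Resample a time series onto a uniform grid
#'
#' Interpolates every channel onto a uniform grid at `target_rate` spanning the
#' original time interval. Linear interpolation is the default; cubic-spline
#' interpolation is used internally where smooth derivatives are needed
#' (inverse dynamics).
#'
#' @param ts a [timeseries()] object with at least 2 samples.
#' @param target_rate new sampling rate in Hz.
#' @param method `"linear"` or `"spline"`.
#' @return A new [timeseries()] at `target_rate`.
#' @export
resample_uniform <- function(ts, target_rate, method = c("linear", "spline")) {
  method <- match.arg(method)
  validate_timeseries(ts, allow_na = TRUE)
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    jw_abort("target_rate must be positive", "jw_argument_error")
  }
  if (ts_n(ts) < 2L) jw_abort("need at least 2 samples to resample", "jw_argument_error")
  t0 <- ts$t[1L]
  t1 <- ts$t[length(ts$t)]
  nout <- floor((t1 - t0) * target_rate + 1e-9) + 1L
  tout <- t0 + (seq_len(nout) - 1) / target_rate
  vout <- matrix(NA_real_, nout, ncol(ts$values), dimnames = dimnames(ts$values))
  for (j in seq_len(ncol(ts$values))) {
    vout[, j] <- if (method == "linear") {
      stats::approx(ts$t, ts$values[, j], xout = tout, rule = 2)$y
    } else {
      stats::spline(ts$t, ts$values[, j], xout = tout, method = "natural")$y
    }
  }
  timeseries(vout, rate = target_rate, t0 = t0, units = ts$units)
}
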