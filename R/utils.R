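#' @keywords internal
"_PACKAGE"

# Standard gravity used throughout (m/s^2).
GRAV <- 9.81

jw_abort <- function(msg, class = "jw_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "jw_error", "error", "condition")))
}

#' Trapezoidal integral of sampled data
#'
#' @param t sample times (strictly increasing numeric vector).
#' @param y sampled values, same length as `t`.
#' @return `trapz()`: the definite integral over `[t[1], t[n]]`.
#'   `cumtrapz()`: the running integral, same length as `t`, starting at 0.
#' @export
trapz <- function(t, y) {
  n <- length(t)
  if (n != length(y)) jw_abort("t and y must have equal length", "jw_argument_error")
  if (n < 2L) return(0)
  sum(diff(t) * (y[-n] + y[-1L]) / 2)
}

#' @rdname trapz
#' @export
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n != length(y)) jw_abort("t and y must have equal length", "jw_argument_error")
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(t) * (y[-n] + y[-1L]) / 2))
}

# Evaluate code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Smootherstep (C2) interpolation weight on [0, 1].
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (u * (u * 6 - 15) + 10)
}

# Cubic Hermite interpolation with endpoint values/velocities.
hermite3 <- function(t, t0, t1, p0, p1, v0 = 0, v1 = 0) {
  s <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  h <- t1 - t0
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * p0 + h10 * h * v0 + h01 * p1 + h11 * h * v1
}

hermite3_deriv <- function(t, t0, t1, p0, p1, v0 = 0, v1 = 0) {
  s <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  h <- t1 - t0
  d00 <- (6 * s^2 - 6 * s) / h
  d10 <- 3 * s^2 - 4 * s + 1
  d01 <- (-6 * s^2 + 6 * s) / h
  d11 <- 3 * s^2 - 2 * s
  d00 * p0 + d10 * v0 + d01 * p1 + d11 * v1
}

# Quintic Hermite interpolation with endpoint values/velocities/accelerations.
hermite5 <- function(t, t0, t1, p0, p1, v0 = 0, v1 = 0, a0 = 0, a1 = 0) {
  h <- t1 - t0
  s <- pmin(pmax((t - t0) / h, 0), 1)
  s2 <- s^2; s3 <- s^3; s4 <- s^4; s5 <- s^5
  H0 <- 1 - 10 * s3 + 15 * s4 - 6 * s5
  H1 <- s - 6 * s3 + 8 * s4 - 3 * s5
  H2 <- 0.5 * s2 - 1.5 * s3 + 1.5 * s4 - 0.5 * s5
  H3 <- 0.5 * s3 - s4 + 0.5 * s5
  H4 <- -4 * s3 + 7 * s4 - 3 * s5
  H5 <- 10 * s3 - 15 * s4 + 6 * s5
  H0 * p0 + H1 * h * v0 + H2 * h^2 * a0 + H3 * h^2 * a1 + H4 * h * v1 + H5 * p1
}

hermite5_deriv <- function(t, t0, t1, p0, p1, v0 = 0, v1 = 0, a0 = 0, a1 = 0) {
  h <- t1 - t0
  s <- pmin(pmax((t - t0) / h, 0), 1)
  s2 <- s^2; s3 <- s^3; s4 <- s^4
  d0 <- (-30 * s2 + 60 * s3 - 30 * s4) / h
  d1 <- 1 - 18 * s2 + 32 * s3 - 15 * s4
  d2 <- (s - 4.5 * s2 + 6 * s3 - 2.5 * s4) * h
  d3 <- (1.5 * s2 - 4 * s3 + 2.5 * s4) * h
  d4 <- -12 * s2 + 28 * s3 - 15 * s4
  d5 <- (30 * s2 - 60 * s3 + 30 * s4) / h
  d0 * p0 + d1 * v0 + d2 * a0 + d3 * a1 + d4 * v1 + d5 * p1
}

# FNV-1a hash of a character string, returned as 8 hex digits (config provenance).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keep h a double (it exceeds .Machine$integer.max)
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact in doubles
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
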