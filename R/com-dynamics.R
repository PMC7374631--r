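# Centre-of-mass energetics from plate force.
#
# COM acceleration comes from Newton's second law (total vertical force over
# body mass), velocity and displacement by forward (trapezoidal) integration.
# COM power is total vertical GRF times vertical COM velocity: the work-loop
# drive is the measured plate force, with gravity accounted for through the
# displacement term of the energy balance. A net-force variant
# (Fz - m g) is available behind `mode = "net"`.

#' COM kinematics by forward dynamics from force
#'
#' @param force_total total vertical force [timeseries()] (one channel, N)
#'   covering the analysis window.
#' @param mass body mass, kg.
#' @param events a `jw_events` from [detect_events()].
#' @param jump_type one of [JUMP_TYPES].
#' @param drop_height drop height in m (sets the drop-jump initial velocity
#'   `-sqrt(2 g h)` at contact; CMJ starts from rest at onset).
#' @param dj_velocity_scale multiplier on the nominal touchdown speed
#'   (step-down technique correction; 1 = nominal).
#' @return An object of class `jw_com_state`: `t`, `a`, `v`, `x` over the
#'   analysis window (displacement relative to the window start).
#' @export
com_kinematics <- function(force_total, mass, events, jump_type,
                           drop_height = 0, dj_velocity_scale = 1) {
  if (mass <= 0) jw_abort("mass must be positive", "jw_argument_error")
  win <- events$window
  t <- force_total$t
  if (win[1L] < t[1L] - 1e-9 || win[2L] > t[length(t)] + 1e-9) {
    jw_abort("force series does not cover the analysis window", "jw_argument_error")
  }
  sel <- which(t >= win[1L] - 1e-9 & t <= win[2L] + 1e-9)
  if (length(sel) < 2L) jw_abort("analysis window is empty", "jw_argument_error")
  tt <- t[sel]
  a <- force_total$values[sel, 1L] / mass - GRAV
  v0 <- if (jump_type == "CMJ") 0 else {
    -dj_velocity_scale * sqrt(2 * GRAV * drop_height)
  }
  v <- v0 + cumtrapz(tt, a)
  x <- cumtrapz(tt, v)
  structure(list(t = tt, a = a, v = v, x = x, idx = sel, mass = mass),
            class = "jw_com_state")
}

new_work_summary <- function(w_neg, w_pos, kind = "com") {
  structure(
    list(W_neg = w_neg, W_pos = w_pos, W_net = w_neg + w_pos,
         ratio = if (w_pos > 0) abs(w_neg) / w_pos * 100 else NA_real_,
         ratio_defined = w_pos > 0, kind = kind),
    class = "jw_work"
  )
}

#' @export
print.jw_work <- function(x, ...) {
  cat(sprintf("<jw_work %s> W- %.3f, W+ %.3f, Wnet %.3f J/kg, ratio %s\n",
              x$kind, x$W_neg, x$W_pos, x$W_net,
              if (x$ratio_defined) sprintf("%.1f%%", x$ratio) else "undefined"))
  invisible(x)
}

#' Negative, positive and net COM work
#'
#' Instantaneous COM power `P = Fz_total * v` (W); negative/positive work are
#' the time integrals of `P` over samples where `P < 0` / `P > 0` within the
#' analysis window, per kilogram of body mass. The partition is by sign of
#' power (identical to descent/ascent for monotone phases, robust to small
#' velocity reversals), and `W_net = W_neg + W_pos` holds exactly.
#'
#' @inheritParams com_kinematics
#' @param state the matching [com_kinematics()] result.
#' @param mode `"total"` (default, drive = measured Fz) or `"net"`
#'   (drive = Fz - m g).
#' @return A `jw_work` summary: `W_neg`, `W_pos`, `W_net` (J/kg) and
#'   `ratio = |W_neg| / W_pos * 100` (%; flagged undefined when `W_pos == 0`).
#' @export
com_work <- function(force_total, state, events, mass,
                     mode = c("total", "net")) {
  mode <- match.arg(mode)
  drive <- force_total$values[state$idx, 1L]
  if (mode == "net") drive <- drive - mass * GRAV
  if (length(drive) != length(state$v)) {
    jw_abort("force and COM state are not sampled consistently", "jw_argument_error")
  }
  P <- drive * state$v / mass
  w_neg <- trapz(state$t, pmin(P, 0))
  w_pos <- trapz(state$t, pmax(P, 0))
  new_work_summary(w_neg, w_pos, kind = "com")
}

#' COM work loop
#'
#' Paired (displacement, force/mass) samples over the analysis window. The
#' signed area enclosed by the loop equals the net COM work up to trapezoidal
#' tolerance.
#'
#' @inheritParams com_work
#' @return A `jw_workloop`: `excursion` (m), `drive` (N/kg), `window`.
#' @export
com_workloop <- function(force_total, state, events, mass,
                         mode = c("total", "net")) {
  mode <- match.arg(mode)
  drive <- force_total$values[state$idx, 1L]
  if (mode == "net") drive <- drive - mass * GRAV
  structure(
    list(excursion = state$x, drive = drive / mass, window = events$window,
         kind = "com"),
    class = "jw_workloop"
  )
}

#' Signed area of a work loop
#'
#' Trapezoidal path integral of drive over excursion. For a closed cycle this
#' is the Green's-theorem enclosed area; for an open loop (e.g. onset to
#' takeoff, which ends displaced from the start) it is the net work, matching
#' the time integral of power up to trapezoidal tolerance.
#'
#' @param loop a `jw_workloop`.
#' @return area in J/kg.
#' @export
workloop_area <- function(loop) {
  x <- loop$excursion
  y <- loop$drive
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2 * diff(x))
}

#' Negative:positive work ratio
#'
#' `|W_neg| / W_pos * 100` (%), the (in)efficiency index of a work loop;
#' values above 100% mean more energy was absorbed than returned.
#'
#' @param w_neg negative work (J/kg, <= 0).
#' @param w_pos positive work (J/kg, >= 0).
#' @return ratio in percent; `NA` (with a warning-free undefined flag
#'   semantics) when `w_pos` is 0.
#' @export
neg_pos_ratio <- function(w_neg, w_pos) {
  if (any(w_pos < 0)) jw_abort("W_pos must be >= 0", "jw_argument_error")
  ifelse(w_pos > 0, abs(w_neg) / w_pos * 100, NA_real_)
}
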