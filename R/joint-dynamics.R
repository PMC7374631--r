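# Bottom-up planar Newton-Euler inverse dynamics.
#
# Per side, the recursion runs foot -> shank -> thigh using that side's plate
# force and centre of pressure; the foot is assumed flat and stationary
# (valid during ground contact, which is the analysis window). Joint moments
# are extensor-positive and normalized to body mass; joint angular velocities
# are extension-positive, so joint power M * omega is positive when the joint
# generates energy (push-off) and negative when it absorbs.
#
# This recursion is written independently of the Lagrangian chain model that
# drives the simulator, so recovering the simulator's ground-truth torques is
# a genuine two-route cross-check.

central_diff <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2L) return(d)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * rate / 2
  d[1L] <- (x[2L] - x[1L]) * rate
  d[n] <- (x[n] - x[n - 1L]) * rate
  d
}

# theta-sense moment of force F applied at lever r (both 2-column matrices or
# vectors (y, z)): r_z F_y - r_y F_z.
mom_th <- function(ry, rz, Fy, Fz) rz * Fy - ry * Fz

#' Planar inverse dynamics of one trial
#'
#' Computes hip/knee/ankle net joint moments for both sides by bottom-up
#' Newton-Euler recursion from each side's plate force and centre of
#' pressure. Joint angles are low-pass filtered (zero-lag Butterworth),
#' resampled to the force rate with a cubic spline, and differentiated by
#' central differences.
#'
#' @param trial a `jw_trial`.
#' @param segparams a [segment_parameters()] object; default built from the
#'   trial's subject with the Winter table.
#' @param filter_cutoff zero-lag low-pass cutoff in Hz applied to angles and
#'   force (`NULL` = no filtering, e.g. for noiseless synthetic data).
#' @param filter_order effective filter order (see [lowpass_zero_lag()]).
#' @return An object of class `jw_joint_kinetics`: for each side (`l`, `r`),
#'   `moment` (N m/kg, channels ankle/knee/hip, extensor-positive), `omega`
#'   (rad/s, extension-positive), `theta` (rad, flexion-positive), all at the
#'   force rate, plus the conventions in `meta`.
#' @export
inverse_dynamics_planar <- function(trial, segparams = NULL,
                                    filter_cutoff = 11, filter_order = 4L) {
  sp <- if (is.null(segparams)) {
    segment_parameters(trial$subject$body_mass, trial$subject$height)
  } else {
    segparams
  }
  mass <- trial$subject$body_mass
  rate <- trial$force$rate
  kin <- trial$kinematics
  force <- trial$force
  if (!is.null(filter_cutoff)) {
    kin <- lowpass_zero_lag(kin, filter_cutoff, filter_order)
    force <- lowpass_zero_lag(force, filter_cutoff, filter_order)
  }
  kin_up <- resample_uniform(kin, rate, method = "spline")
  n <- min(ts_n(kin_up), ts_n(force))
  # single-leg segment constants
  m_f <- sp$foot$m; m_s <- sp$shank$m; m_t <- sp$thigh$m
  Ls <- sp$shank$L; Lt <- sp$thigh$L
  r1 <- (1 - sp$shank$com) * Ls     # ankle -> shank COM
  r2 <- (1 - sp$thigh$com) * Lt     # knee -> thigh COM
  I1 <- sp$shank$I; I2 <- sp$thigh$I
  zA <- sp$ankle_height; ycf <- sp$foot_com_y
  out <- list()
  for (side in c("l", "r")) {
    hipq <- kin_up$values[seq_len(n), paste0("hip_", side)]
    kneeq <- kin_up$values[seq_len(n), paste0("knee_", side)]
    ankq <- kin_up$values[seq_len(n), paste0("ankle_", side)]
    th1 <- ankq
    th2 <- th1 - kneeq
    th3 <- th2 + hipq
    th1d <- central_diff(th1, rate); th1dd <- central_diff(th1d, rate)
    th2d <- central_diff(th2, rate); th2dd <- central_diff(th2d, rate)
    th3d <- central_diff(th3, rate)
    Fy <- force$values[seq_len(n), paste0("fy_", side)]
    Fz <- force$values[seq_len(n), paste0("fz_", side)]
    cop <- force$values[seq_len(n), paste0("cop_", side)]
    # foot (static): moment balance about the ankle
    T_fs <- -zA * Fy - cop * Fz + ycf * m_f * GRAV
    F_fs_y <- Fy
    F_fs_z <- Fz - m_f * GRAV
    # shank
    s1 <- sin(th1); c1 <- cos(th1)
    a1y <- r1 * (th1dd * c1 - th1d^2 * s1)
    a1z <- r1 * (-th1dd * s1 - th1d^2 * c1)
    F_ks_y <- m_s * a1y - F_fs_y
    F_ks_z <- m_s * a1z - F_fs_z + m_s * GRAV
    T_ks <- I1 * th1dd - T_fs -
      mom_th(-r1 * s1, -r1 * c1, F_fs_y, F_fs_z) -
      mom_th((Ls - r1) * s1, (Ls - r1) * c1, F_ks_y, F_ks_z)
    # thigh
    s2 <- sin(th2); c2 <- cos(th2)
    a2y <- Ls * (th1dd * c1 - th1d^2 * s1) + r2 * (th2dd * c2 - th2d^2 * s2)
    a2z <- Ls * (-th1dd * s1 - th1d^2 * c1) + r2 * (-th2dd * s2 - th2d^2 * c2)
    F_ht_y <- m_t * a2y + F_ks_y
    F_ht_z <- m_t * a2z + F_ks_z + m_t * GRAV
    T_ht <- I2 * th2dd + T_ks -
      mom_th(-r2 * s2, -r2 * c2, -F_ks_y, -F_ks_z) -
      mom_th((Lt - r2) * s2, (Lt - r2) * c2, F_ht_y, F_ht_z)
    moment <- cbind(ankle = -T_fs / mass, knee = -T_ks / mass, hip = T_ht / mass)
    omega <- cbind(ankle = -th1d, knee = th2d - th1d, hip = th2d - th3d)
    theta <- cbind(ankle = ankq, knee = kneeq, hip = hipq)
    out[[side]] <- list(
      moment = timeseries(moment, rate, t0 = kin_up$t[1L], units = "N m/kg"),
      omega = timeseries(omega, rate, t0 = kin_up$t[1L], units = "rad/s"),
      theta = timeseries(theta, rate, t0 = kin_up$t[1L], units = "rad")
    )
  }
  structure(
    list(l = out$l, r = out$r, mass = mass,
         meta = list(moments = "extensor-positive, per kg body mass",
                     omega = "extension-positive",
                     filter_cutoff = filter_cutoff)),
    class = "jw_joint_kinetics"
  )
}

JOINTS <- c("hip", "knee", "ankle")

#' Per-joint, per-side work summaries
#'
#' Joint power `P_j = M_j * omega_j` (W/kg; both extensor-positive, so the
#' sign-partitioned time integral over the analysis window equals the area
#' under the moment-angular-displacement curve). Negative/positive work by
#' sign of instantaneous power, as for the COM.
#'
#' @param kin a [inverse_dynamics_planar()] result.
#' @param events a `jw_events`.
#' @return Nested list `side -> joint -> jw_work` (J/kg).
#' @export
joint_work <- function(kin, events) {
  win <- events$window
  if (diff(win) <= 0) jw_abort("zero-length analysis window", "jw_argument_error")
  out <- list()
  for (side in c("l", "r")) {
    t <- kin[[side]]$moment$t
    sel <- which(t >= win[1L] - 1e-9 & t <= win[2L] + 1e-9)
    if (length(sel) < 2L) jw_abort("analysis window not covered by kinetics", "jw_argument_error")
    out[[side]] <- list()
    for (j in JOINTS) {
      P <- kin[[side]]$moment$values[sel, j] * kin[[side]]$omega$values[sel, j]
      w_neg <- trapz(t[sel], pmin(P, 0))
      w_pos <- trapz(t[sel], pmax(P, 0))
      out[[side]][[j]] <- new_work_summary(w_neg, w_pos, kind = j)
    }
  }
  out
}

#' Bilateral average of two work summaries
#'
#' Arithmetic mean of the negative, positive and net components of the left
#' and right summaries of the same joint; the negative:positive ratio is
#' recomputed from the averaged components (the ratio of averages, not the
#' average of ratios).
#'
#' @param left,right `jw_work` objects for the same joint.
#' @return A `jw_work`.
#' @export
bilateral_average <- function(left, right) {
  if (!identical(left$kind, right$kind)) {
    jw_abort(sprintf("cannot average different joints ('%s' vs '%s')",
                     left$kind, right$kind), "jw_argument_error")
  }
  new_work_summary((left$W_neg + right$W_neg) / 2,
                   (left$W_pos + right$W_pos) / 2,
                   kind = left$kind)
}

#' Joint work loop (moment vs angle)
#'
#' @param kin a [inverse_dynamics_planar()] result.
#' @param events a `jw_events`.
#' @param side `"l"` or `"r"`.
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @return A `jw_workloop` with `excursion` = extension angle displacement
#'   (rad, so that drive x excursion area matches the work sign convention)
#'   and `drive` = moment (N m/kg).
#' @export
joint_workloop <- function(kin, events, side, joint) {
  side <- match.arg(side, c("l", "r"))
  joint <- match.arg(joint, JOINTS)
  win <- events$window
  t <- kin[[side]]$moment$t
  sel <- which(t >= win[1L] - 1e-9 & t <= win[2L] + 1e-9)
  theta0 <- kin[[side]]$theta$values[sel[1L], joint]
  structure(
    list(excursion = -(kin[[side]]$theta$values[sel, joint] - theta0),
         drive = kin[[side]]$moment$values[sel, joint],
         window = win, kind = joint),
    class = "jw_workloop"
  )
}
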