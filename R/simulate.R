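# Torque-driven planar jump simulator.
#
# A trial is assembled from phases:
#   quiet standing (CMJ)  - exact static equilibrium, GRF = m g
#   flight-in (DJ)        - ballistic COM, smooth joint templates; the
#                           touchdown joint velocities are solved so the ankle
#                           point has zero world velocity at contact (no
#                           impulsive collision)
#   contact               - torque-driven forward dynamics (RK4, fixed step) of
#                           the shank-thigh-HAT chain on a fixed flat foot,
#                           with PD servo torques around keyframed joint-angle
#                           templates, gravity feedforward and a smooth tanh
#                           torque saturation scaled by subject strength
#   flight-out            - ballistic COM, joints blend to a hold posture;
#                           ends at the landing touch
#
# Ground-truth joint torques (per side) are recorded during contact and are NA
# during flight, where bottom-up inverse dynamics from plate force is not
# defined.

KIN_RATE <- 200
FORCE_RATE <- 1000

#' Default actuation (torque-template) parameters
#'
#' Keyframed joint-angle templates and PD-servo settings used by
#' [simulate_trial()]. Angles are flexion-positive (ankle dorsiflexion, knee
#' flexion, hip flexion) in radians, ordered (ankle, knee, hip). Torque caps
#' are for the whole chain (both legs) and scale with body mass and relative
#' strength, so weaker subjects saturate earlier and absorb relatively more
#' energy in deep drop jumps.
#'
#' @param subject a `jw_subject`.
#' @param drop_height drop height in m (0 for CMJ).
#' @return named list of template and servo parameters.
#' @export
default_actuation <- function(subject, drop_height = 0) {
  bm <- subject$body_mass
  rel <- subject$rel_strength
  list(
    q_stand = c(0.08, 0.15, 0.15),
    cmj_depth = c(0.50, 1.50, 1.40),
    # landing posture and stance depth deepen with eccentric load: with a flat
    # fixed foot, absorbing the touchdown velocity needs flexed joints
    dj_depth = c(0.40, 1.25, 1.15) + c(0.30, 0.85, 0.85) * drop_height,
    q_takeoff = c(0.00, -0.03, -0.03),
    q_stepoff = c(0.05, 0.35, 0.35),
    q_touchdown = c(0.20, 0.55, 0.50) + c(0.30, 1.20, 1.00) * drop_height,
    t_quiet = 0.4,
    cm_dur = 0.45, prop_dur = 0.20,
    absorb_dur = 0.18 + 0.15 * drop_height, push_dur = 0.26,
    land_blend = 0.20,
    kp = bm * c(24, 60, 60),
    kd = bm * c(2.4, 6.0, 6.0),
    tau_max = bm * (c(2.0, 3.0, 3.0) + c(1.5, 2.5, 2.5) * rel),
    # passive joint-limit structures (not strength-capped): quadratic spring
    # plus penetration-scaled damping outside the range of motion
    q_min = c(-0.60, -0.10, -0.30),
    q_max = c(0.65, 2.40, 2.20),
    k_lim = bm * 80, c_lim = bm * 4,
    # ankle-strategy balance feedback, active only once the COM leaves the
    # foot support region [bal_lo, bal_hi] (m, relative to the ankle):
    # quadratic spring + penetration-scaled damping, like the joint limits
    k_bal = bm * 150, d_bal = bm * 30,
    bal_lo = NA, bal_hi = NA,   # filled per trial from foot geometry

    depth_jitter = 0.03, time_jitter = 0.03
  )
}

# Piecewise joint-space reference: keyframes is a list of entries
# list(t, q, qd); between keyframes cubic Hermite. Returns function(t) ->
# list(q, qd).
make_template <- function(keys) {
  tk <- vapply(keys, `[[`, 0, "t")
  function(t) {
    if (t <= tk[1L]) {
      return(list(q = keys[[1L]]$q, qd = keys[[1L]]$qd))
    }
    if (t >= tk[length(tk)]) {
      return(list(q = keys[[length(keys)]]$q, qd = keys[[length(keys)]]$qd))
    }
    i <- findInterval(t, tk)
    k0 <- keys[[i]]; k1 <- keys[[i + 1L]]
    q <- hermite3(t, k0$t, k1$t, k0$q, k1$q, k0$qd, k1$qd)
    qd <- hermite3_deriv(t, k0$t, k1$t, k0$q, k1$q, k0$qd, k1$qd)
    list(q = q, qd = qd)
  }
}

# Absorption reference: joint velocity decays exponentially from the
# touchdown rate (time constant tb) while the posture blends into the stance
# depth over `dur`. The immediate reference deceleration makes the servo brake
# from the first instant of contact, which keeps GRF non-negative.
make_absorb_template <- function(t0, q0, qd0, depth, dur, tb = dur / 4) {
  function(t) {
    s <- max(t - t0, 0)
    b <- q0 + qd0 * tb * (1 - exp(-s / tb))
    bd <- qd0 * exp(-s / tb)
    u <- min(s / dur, 1)
    w <- smoothstep5(u)
    wd <- if (u >= 1) 0 else 30 * u^2 * (1 - u)^2 / dur
    list(q = (1 - w) * b + w * depth,
         qd = (1 - w) * bd + wd * (depth - b))
  }
}

# PD servo with gravity feedforward, ankle-strategy balance feedback and
# smooth saturation. q/qd are joint (flexion-positive) coordinates; torques
# extensor-positive. The balance term steers the ankle so the whole-body COM
# stays over the foot (y_ref forward of the ankle): a plantarflexor
# correction when the COM drifts forward, dorsiflexor when it falls behind —
# without it the angle-tracking chain can topple during heavy landings.
make_servo <- function(cm, act, template) {
  force(template)
  function(t, th, thd) {
    ref <- template(t)
    qj <- joint_from_seg(th)
    qdj <- c(thd[1L], thd[1L] - thd[2L], thd[3L] - thd[2L])
    ff <- chain_static_tau(cm, th)
    com <- chain_com(cm, th, thd)
    over <- max(com$pos[1L] - act$bal_hi, 0)
    under <- max(act$bal_lo - com$pos[1L], 0)
    bal <- act$k_bal * (over^2 - under^2) +
      act$d_bal * com$vel[1L] * (over + under)
    raw <- act$kp * (qj - ref$q) + act$kd * (qdj - ref$qd) + ff
    # balance sits outside the strength cap, like the passive structures:
    # heel/forefoot contact mechanics, not muscle, supply that moment
    act$tau_max * tanh(raw / act$tau_max) + passive_limit_tau(act, qj, qdj) +
      c(bal, 0, 0)
  }
}

# Passive joint-limit torque (extensor-positive, C1-smooth): quadratic spring
# beyond the range of motion, damping proportional to penetration depth.
passive_limit_tau <- function(act, qj, qdj) {
  over <- pmax(qj - act$q_max, 0)
  under <- pmax(act$q_min - qj, 0)
  act$k_lim * over^2 - act$k_lim * under^2 +
    act$c_lim * qdj * (over + under)
}

# Record of one trial phase at the force rate.
empty_rec <- function() {
  list(t = numeric(), th = NULL, thd = NULL, tau = NULL,
       fy = numeric(), fz = numeric(), cop = numeric(),
       com_z = numeric(), com_v = numeric(), com_a = numeric(),
       contact = logical())
}

rec_bind <- function(...) {
  parts <- list(...)
  out <- empty_rec()
  out$t <- unlist(lapply(parts, `[[`, "t"))
  for (f in c("th", "thd", "tau")) out[[f]] <- do.call(rbind, lapply(parts, `[[`, f))
  for (f in c("fy", "fz", "cop", "com_z", "com_v", "com_a", "contact")) {
    out[[f]] <- unlist(lapply(parts, `[[`, f))
  }
  out
}

# Contact-phase integration, recording at the force rate. By default stops at
# takeoff: the first recorded sample with Fz <= 0 while the COM moves upward
# (transient unloading dips during the movement are not takeoffs). A custom
# `stop_fun(t, th, thd, grf, com)` ends the stage without recording the
# boundary sample, so a following stage can resume seamlessly at (t, y).
# Errors (naming the phase) on divergence or after max_dur.
run_contact <- function(cm, y0, t0, tau_fun, sim_rate, max_dur, t_min = t0,
                        phase = "contact", stop_fun = NULL) {
  h <- 1 / sim_rate
  nsub <- as.integer(round(sim_rate / FORCE_RATE))
  rec <- list(t = numeric(), th = list(), thd = list(), tau = list(),
              fy = numeric(), fz = numeric(), cop = numeric(),
              com_z = numeric(), com_v = numeric(), com_a = numeric())
  y <- y0
  t <- t0
  i <- 0L
  takeoff <- NA_real_
  repeat {
    if (!all(is.finite(y))) {
      jw_abort(sprintf("simulation diverged during %s phase at t = %.3f s", phase, t),
               "jw_simulation_error")
    }
    th <- y[1:3]; thd <- y[4:6]
    tau <- tau_fun(t, th, thd)
    qdd <- chain_qdd(cm, th, thd, tau)
    grf <- chain_grf(cm, th, thd, qdd)
    com <- chain_com(cm, th, thd, qdd)
    if (!is.null(stop_fun) && t > t_min && stop_fun(t, th, thd, grf, com)) {
      return(list(
        rec = list(
          t = rec$t, th = do.call(rbind, rec$th), thd = do.call(rbind, rec$thd),
          tau = do.call(rbind, rec$tau), fy = rec$fy, fz = rec$fz, cop = rec$cop,
          com_z = rec$com_z, com_v = rec$com_v, com_a = rec$com_a,
          contact = rep(TRUE, length(rec$t))
        ),
        y_end = y, t_end = t, t_takeoff = NA_real_,
        state_takeoff = NULL
      ))
    }
    i <- i + 1L
    rec$t[i] <- t
    rec$th[[i]] <- th; rec$thd[[i]] <- thd; rec$tau[[i]] <- tau
    rec$fy[i] <- grf[["Fy"]]; rec$fz[i] <- grf[["Fz"]]
    rec$cop[i] <- chain_cop(cm, tau[1L], grf[["Fy"]], grf[["Fz"]])
    rec$com_z[i] <- cm$ankle_height + com$pos[2L]
    rec$com_v[i] <- com$vel[2L]
    rec$com_a[i] <- com$acc[2L]
    if (grf[["Fz"]] <= 0 && com$vel[2L] > 0.1 && t > t_min) {
      takeoff <- t
      break
    }
    if (t - t0 > max_dur) {
      jw_abort(sprintf("no takeoff within %.1f s of %s phase start", max_dur, phase),
               "jw_simulation_error")
    }
    for (s in seq_len(nsub)) {
      y <- rk4_step(cm, t, y, h, tau_fun)
      t <- t + h
    }
    t <- t0 + round((t - t0) * FORCE_RATE) / FORCE_RATE  # keep the grid exact
  }
  n <- length(rec$t)
  # the sample at which Fz crossed zero is the first flight sample
  rec$fz[n] <- 0; rec$fy[n] <- 0; rec$cop[n] <- 0
  rec$tau[[n]] <- rep(NA_real_, 3)
  rec$com_a[n] <- -GRAV
  list(
    rec = list(
      t = rec$t, th = do.call(rbind, rec$th), thd = do.call(rbind, rec$thd),
      tau = do.call(rbind, rec$tau), fy = rec$fy, fz = rec$fz, cop = rec$cop,
      com_z = rec$com_z, com_v = rec$com_v, com_a = rec$com_a,
      contact = c(rep(TRUE, n - 1L), FALSE)
    ),
    y_end = y, t_end = t, t_takeoff = takeoff,
    state_takeoff = list(th = y[1:3], thd = y[4:6])
  )
}

# Kinematic flight phase on the force-rate grid of [t0, t1): ballistic COM,
# joint angles from a segment-space template. GRF identically zero, torques NA.
run_flight <- function(cm, t0, t1, theta_fun, z0, v0) {
  tg <- seq(t0, t1 - 1e-9, by = 1 / FORCE_RATE)
  n <- length(tg)
  th <- matrix(0, n, 3); thd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- theta_fun(tg[i])
    th[i, ] <- s$q; thd[i, ] <- s$qd
  }
  dt <- tg - t0
  list(
    t = tg, th = th, thd = thd, tau = matrix(NA_real_, n, 3),
    fy = rep(0, n), fz = rep(0, n), cop = rep(0, n),
    com_z = z0 + v0 * dt - 0.5 * GRAV * dt^2,
    com_v = v0 - GRAV * dt,
    com_a = rep(-GRAV, n),
    contact = rep(FALSE, n)
  )
}

# Static standing record over [t0, t1).
run_quiet <- function(cm, th0, t0, t1) {
  tg <- seq(t0, t1 - 1e-9, by = 1 / FORCE_RATE)
  n <- length(tg)
  tau0 <- chain_static_tau(cm, th0)
  fz <- cm$m_tot * GRAV
  com <- chain_com(cm, th0, c(0, 0, 0))
  list(
    t = tg,
    th = matrix(th0, n, 3, byrow = TRUE), thd = matrix(0, n, 3),
    tau = matrix(tau0, n, 3, byrow = TRUE),
    fy = rep(0, n), fz = rep(fz, n),
    cop = rep(chain_cop(cm, tau0[1L], 0, fz), n),
    com_z = rep(cm$ankle_height + com$pos[2L], n),
    com_v = rep(0, n), com_a = rep(0, n),
    contact = rep(TRUE, n)
  )
}

# Time (relative) at which the ankle returns to ground level in ballistic
# flight with the chain frozen at configuration th_hold.
flight_duration <- function(cm, th_hold, z0, v0) {
  r_z <- chain_com(cm, th_hold, c(0, 0, 0))$pos[2L]
  # solve z0 + v0 t - g t^2 / 2 = ankle_height + r_z for the larger root
  cc <- z0 - cm$ankle_height - r_z
  disc <- v0^2 + 2 * GRAV * cc
  if (disc < 0) return(0.05)
  (v0 + sqrt(disc)) / GRAV
}

#' Simulate one jump trial
#'
#' Torque-driven forward dynamics of a planar four-segment
#' (foot-shank-thigh-HAT) model performing a countermovement or drop jump,
#' sampled like a laboratory trial: per-plate vertical and anterior-posterior
#' ground reaction force and centre of pressure at 1,000 Hz, bilateral
#' hip/knee/ankle flexion angles at 200 Hz, plus ground-truth joint torques and
#' COM states. The model is bilaterally symmetric: each plate carries half the
#' total force and per-side truth torques are half the chain torques.
#'
#' @param subject a `jw_subject` from [generate_cohort()].
#' @param jump_type one of [JUMP_TYPES].
#' @param drop_height drop height in m; defaults to the nominal height of
#'   `jump_type`.
#' @param actuation named list overriding [default_actuation()] entries.
#' @param sim_rate integrator rate in Hz (>= 1,000, multiple of 1,000).
#' @param seed integer seed for the (small) trial-to-trial template jitter.
#' @return A `jw_trial` (see [new_trial()]) with a `truth` element:
#'   `torque` (per-side N m, NA in flight), `com` (absolute height, velocity,
#'   acceleration of the COM), `state` (segment angles/rates), and `events`
#'   (true movement-start/contact/takeoff/landing times).
#' @export
simulate_trial <- function(subject, jump_type, drop_height = NULL,
                           actuation = list(), sim_rate = 1000, seed = 1L) {
  jump_type <- match.arg(jump_type, JUMP_TYPES)
  if (is.null(drop_height)) drop_height <- jump_drop_height(jump_type)
  if (drop_height < 0) jw_abort("drop_height must be >= 0", "jw_argument_error")
  if (sim_rate < 1000 || round(sim_rate) %% FORCE_RATE != 0) {
    jw_abort("sim_rate must be a multiple of 1,000 Hz, >= 1,000 Hz", "jw_argument_error")
  }
  if (jump_type != "CMJ" && drop_height <= 0) {
    jw_abort("drop jumps need a positive drop height", "jw_argument_error")
  }
  sp <- segment_parameters(subject$body_mass, subject$height)
  cm <- chain_model(sp)
  act <- utils::modifyList(default_actuation(subject, drop_height), actuation)
  if (is.na(act$bal_lo)) act$bal_lo <- 0.8 * sp$heel_y
  if (is.na(act$bal_hi)) act$bal_hi <- 0.85 * sp$toe_y
  # deterministic trial-to-trial variability on depth and timing
  jit <- with_seed(seed, stats::rnorm(4))
  depth_scale <- 1 + act$depth_jitter * jit[1L]
  time_scale <- pmax(1 + act$time_jitter * jit[2:3], 0.7)

  if (jump_type == "CMJ") {
    th0 <- seg_from_joint(act$q_stand)
    t_move <- act$t_quiet
    cm_dur <- act$cm_dur * time_scale[1L]
    prop_dur <- act$prop_dur * time_scale[2L]
    quiet <- run_quiet(cm, th0, 0, t_move)
    con <- NULL
    for (vigor in c(1, 0.75, 0.55)) {
      tpl <- make_template(list(
        list(t = t_move, q = act$q_stand, qd = c(0, 0, 0)),
        list(t = t_move + cm_dur, q = act$cmj_depth * depth_scale, qd = c(0, 0, 0)),
        list(t = t_move + cm_dur + prop_dur * vigor, q = act$q_takeoff, qd = c(0, 0, 0))
      ))
      servo <- make_servo(cm, act, tpl)
      con <- tryCatch(
        run_contact(cm, c(th0, 0, 0, 0), t_move, servo, sim_rate,
                    max_dur = cm_dur + prop_dur + 1.0,
                    t_min = t_move + 0.05, phase = "CMJ contact"),
        jw_simulation_error = function(e) e
      )
      if (!inherits(con, "error")) break
    }
    if (inherits(con, "error")) stop(con)
    parts <- list(quiet, con$rec)
    t_contact_true <- NA_real_
    t_move_true <- t_move
  } else {
    # touchdown must fall on the force-rate grid; the rounding (<= 0.5 ms)
    # shifts touchdown speed by < 0.2% of sqrt(2 g h)
    t_fall <- max(round(sqrt(2 * drop_height / GRAV) * FORCE_RATE), 2) / FORCE_RATE
    th_so <- seg_from_joint(act$q_stepoff)
    th_td <- seg_from_joint(act$q_touchdown)
    v_td <- GRAV * t_fall
    Jr <- chain_com_jacobian(cm, th_td)
    thd_td <- drop(t(Jr) %*% solve(Jr %*% t(Jr), c(0, -v_td)))
    z_td <- cm$ankle_height + chain_com(cm, th_td, c(0, 0, 0))$pos[2L]
    z0 <- z_td + 0.5 * GRAV * t_fall^2
    qd_joint_td <- c(thd_td[1L], thd_td[1L] - thd_td[2L], thd_td[3L] - thd_td[2L])
    # match the flight template's end acceleration to the contact dynamics at
    # touchdown so sampled kinematics are C2 through the model switch
    absorb0 <- (0.14 + 0.11 * v_td) * pmax(1 + act$time_jitter * jit[2L], 0.7)
    abs_tpl0 <- make_absorb_template(t_fall, act$q_touchdown, qd_joint_td,
                                     act$dj_depth * depth_scale, absorb0)
    servo_td <- make_servo(cm, act, abs_tpl0)
    thdd_td <- chain_qdd(cm, th_td, thd_td, servo_td(t_fall, th_td, thd_td))
    fl_tpl <- function(t) {
      list(q = hermite5(t, 0, t_fall, th_so, th_td, 0, thd_td, 0, thdd_td),
           qd = hermite5_deriv(t, 0, t_fall, th_so, th_td, 0, thd_td, 0, thdd_td))
    }
    flight_in <- run_flight(cm, 0, t_fall, fl_tpl, z0, 0)
    # absorption time scales with touchdown speed so torque demand stays
    # within the strength-scaled caps; the push stage starts from whatever
    # state absorption actually reached, once the descent is arrested
    absorb <- absorb0
    # start the push once the descent is essentially arrested; the hard time
    # bound keeps an unbalanced chain (no balance controller exists) from
    # settling into a toppled rest state before the push begins
    stageA <- run_contact(cm, c(th_td, thd_td), t_fall,
                          servo_td, sim_rate,
                          max_dur = absorb + 1.0, t_min = t_fall + 0.05,
                          phase = "DJ absorption",
                          stop_fun = function(t, th, thd, grf, com) {
                            com$vel[2L] > -0.1 || t > t_fall + absorb + 0.25
                          })
    qj_b <- joint_from_seg(stageA$y_end[1:3])
    qdj_b <- c(stageA$y_end[4L], stageA$y_end[4L] - stageA$y_end[5L],
               stageA$y_end[6L] - stageA$y_end[5L])
    # a too-leisurely push can settle into standing without ever unloading the
    # plates; retry the push faster (a more vigorous attempt), as a jumper would
    push0 <- (0.18 + 0.10 * qj_b[2L]) * time_scale[2L]
    con <- NULL
    # the last resorts push faster and "through" full extension (slight
    # hyperextension target into the passive limits), which guarantees the
    # sharp terminal deceleration that unloads the plates
    ladder <- list(c(1, 0), c(0.75, 0), c(0.55, 0), c(0.4, 0.12), c(0.3, 0.12))
    for (lv in ladder) {
      push <- push0 * lv[1L]
      push_tpl <- make_template(list(
        list(t = stageA$t_end, q = qj_b, qd = qdj_b),
        list(t = stageA$t_end + push, q = act$q_takeoff - lv[2L], qd = c(0, 0, 0))
      ))
      servo <- make_servo(cm, act, push_tpl)
      con <- tryCatch(
        run_contact(cm, stageA$y_end, stageA$t_end, servo, sim_rate,
                    max_dur = push + 1.0, t_min = stageA$t_end + 0.02,
                    phase = "DJ push"),
        jw_simulation_error = function(e) e
      )
      if (!inherits(con, "error")) break
    }
    if (inherits(con, "error")) stop(con)
    con$rec <- rec_bind(stageA$rec, con$rec)
    parts <- list(flight_in, con$rec)
    t_contact_true <- t_fall
    t_move_true <- NA_real_
  }

  # flight out: blend joints to a hold posture, ballistic COM, end at landing
  th_to <- con$state_takeoff$th
  thd_to <- con$state_takeoff$thd
  thdd_to <- chain_qdd(cm, th_to, thd_to, servo(con$t_takeoff, th_to, thd_to))
  th_hold <- seg_from_joint(c(0.05, 0.25, 0.25))
  n_rec <- length(con$rec$t)
  z_to <- con$rec$com_z[n_rec]
  v_to <- con$rec$com_v[n_rec]
  t_to <- con$t_takeoff
  t_bl <- t_to + act$land_blend
  out_tpl <- function(t) {
    list(q = hermite5(t, t_to, t_bl, th_to, th_hold, thd_to, 0, thdd_to, 0),
         qd = hermite5_deriv(t, t_to, t_bl, th_to, th_hold, thd_to, 0, thdd_to, 0))
  }
  t_air <- flight_duration(cm, th_hold, z_to, v_to)
  t_land <- con$t_takeoff + max(t_air, 2 / FORCE_RATE)
  flight_out <- run_flight(cm, con$t_takeoff + 1 / FORCE_RATE, t_land, out_tpl,
                           z_to + v_to / FORCE_RATE - 0.5 * GRAV / FORCE_RATE^2,
                           v_to - GRAV / FORCE_RATE)
  rec <- rec_bind(parts[[1L]], parts[[2L]], flight_out)

  # regularize the grid (floating-point time arithmetic) and package the trial
  nr <- length(rec$t)
  stopifnot(max(abs(diff(rec$t) - 1 / FORCE_RATE)) < 1e-6)
  qj <- cbind(rec$th[, 3L] - rec$th[, 2L],               # hip flexion
              rec$th[, 1L] - rec$th[, 2L],               # knee flexion
              rec$th[, 1L])                              # ankle dorsiflexion
  force_ts <- timeseries(
    cbind(fz_l = rec$fz / 2, fy_l = rec$fy / 2, cop_l = rec$cop,
          fz_r = rec$fz / 2, fy_r = rec$fy / 2, cop_r = rec$cop),
    rate = FORCE_RATE, units = "N; CoP m"
  )
  kin_idx <- seq(1L, nr, by = FORCE_RATE / KIN_RATE)
  kin_ts <- timeseries(
    cbind(hip_l = qj[kin_idx, 1L], knee_l = qj[kin_idx, 2L], ankle_l = qj[kin_idx, 3L],
          hip_r = qj[kin_idx, 1L], knee_r = qj[kin_idx, 2L], ankle_r = qj[kin_idx, 3L]),
    rate = KIN_RATE, units = "rad"
  )
  truth <- list(
    torque = timeseries(
      cbind(ankle_l = rec$tau[, 1L] / 2, knee_l = rec$tau[, 2L] / 2,
            hip_l = rec$tau[, 3L] / 2,
            ankle_r = rec$tau[, 1L] / 2, knee_r = rec$tau[, 2L] / 2,
            hip_r = rec$tau[, 3L] / 2),
      rate = FORCE_RATE, units = "N m"
    ),
    com = timeseries(cbind(z = rec$com_z, v = rec$com_v, a = rec$com_a),
                     rate = FORCE_RATE, units = "m; m/s; m/s^2"),
    state = timeseries(cbind(th1 = rec$th[, 1L], th2 = rec$th[, 2L], th3 = rec$th[, 3L],
                             thd1 = rec$thd[, 1L], thd2 = rec$thd[, 2L],
                             thd3 = rec$thd[, 3L]),
                       rate = FORCE_RATE, units = "rad; rad/s"),
    contact = rec$contact,
    events = list(t_move = t_move_true, t_contact = t_contact_true,
                  t_takeoff = con$t_takeoff, t_land = t_land,
                  v_touchdown = if (jump_type == "CMJ") NA_real_ else -GRAV * sqrt(2 * drop_height / GRAV)),
    segparams = sp
  )
  new_trial(subject = subject, jump_type = jump_type, drop_height = drop_height,
            force = force_ts, kinematics = kin_ts, truth = truth,
            meta = list(sim_rate = sim_rate, seed = seed, noise = c(force_sd = 0, angle_sd = 0)))
}

#' Add measurement noise to a simulated trial
#'
#' Adds i.i.d. Gaussian noise to the force channels (N) and the joint-angle
#' channels (rad). Ground-truth channels are untouched. Deterministic given
#' `seed`.
#'
#' @param trial a `jw_trial`.
#' @param force_sd per-sample force noise SD in N (per plate channel).
#' @param angle_sd per-sample angle noise SD in rad.
#' @param seed integer seed.
#' @return The noisy trial.
#' @export
add_noise <- function(trial, force_sd = 0, angle_sd = 0, seed = 1L) {
  if (force_sd < 0 || angle_sd < 0) {
    jw_abort("noise SDs must be >= 0", "jw_argument_error")
  }
  with_seed(seed, {
    fcols <- c("fz_l", "fy_l", "fz_r", "fy_r")
    if (force_sd > 0) {
      for (cc in fcols) {
        trial$force$values[, cc] <- trial$force$values[, cc] +
          stats::rnorm(ts_n(trial$force), 0, force_sd)
      }
    }
    if (angle_sd > 0) {
      for (cc in colnames(trial$kinematics$values)) {
        trial$kinematics$values[, cc] <- trial$kinematics$values[, cc] +
          stats::rnorm(ts_n(trial$kinematics), 0, angle_sd)
      }
    }
  })
  trial$meta$noise <- c(force_sd = force_sd, angle_sd = angle_sd)
  trial
}
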