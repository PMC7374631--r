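# Planar dynamics of the foot-shank-thigh-HAT chain during ground contact.
#
# During contact the foot is fixed flat on the ground and the three remaining
# segments form a triple inverted pendulum pinned at the ankle. Segment
# orientations th = (shank, thigh, HAT) are measured from the vertical,
# positive = forward lean; u(th) = (sin th, cos th) points from the segment's
# distal joint towards its proximal end.
#
# With r[k, j] the (constant) coefficient of u_j in the position of segment
# k's COM relative to the ankle, the equations of motion have the closed form
#   sum_j M_ij thdd_j = Q_i + G_i - C_i
#   M_ij = S_ij cos(th_i - th_j) + delta_ij I_i,  S_ij = sum_k m_k r_ki r_kj
#   C_i  = -sum_j S_ij thd_j^2 sin(th_j - th_i)
#   G_i  = g sin(th_i) sum_k m_k r_ki
# This Lagrangian route is deliberately independent of the bottom-up
# Newton-Euler recursion used by the analysis-side inverse dynamics, so torque
# recovery is a genuine cross-check.
#
# Joint angles are flexion-positive (ankle dorsiflexion a, knee flexion k, hip
# flexion h); with the foot flat: a = th1, k = th1 - th2, h = th3 - th2.
# Joint torques tau = (ankle, knee, hip) are extensor-positive; the virtual
# work mapping to generalized torques is Q = A tau with rows
# (-1,-1,0), (0,1,1), (0,0,-1).

A_TAU <- rbind(c(-1, -1, 0), c(0, 1, 1), c(0, 0, -1))

# Chain model: both legs lumped (leg segments doubled), HAT on top.
chain_model <- function(sp) {
  m <- c(2 * sp$shank$m, 2 * sp$thigh$m, sp$hat$m)
  I <- c(2 * sp$shank$I, 2 * sp$thigh$I, sp$hat$I)
  r <- matrix(0, 3, 3)
  r[1, 1] <- (1 - sp$shank$com) * sp$shank$L
  r[2, 1] <- sp$shank$L
  r[2, 2] <- (1 - sp$thigh$com) * sp$thigh$L
  r[3, 1] <- sp$shank$L
  r[3, 2] <- sp$thigh$L
  r[3, 3] <- sp$hat$com * sp$hat$L
  S <- t(r) %*% (m * r)
  mr <- colSums(m * r)
  m_foot <- 2 * sp$foot$m
  list(
    sp = sp, m = m, I = I, r = r, S = S, mr = mr,
    m_foot = m_foot, m_tot = sum(m) + m_foot,
    # foot COM relative to the ankle joint (both feet)
    foot_com = c(sp$foot_com_y, sp$foot_com_z - sp$ankle_height),
    ankle_height = sp$ankle_height
  )
}

joint_from_seg <- function(th) c(th[1L], th[1L] - th[2L], th[3L] - th[2L]) # a, k, h
seg_from_joint <- function(j) c(j[1L], j[1L] - j[2L], j[1L] - j[2L] + j[3L])

# Forward dynamics: segment angular accelerations for given joint torques.
chain_qdd <- function(cm, th, thd, tau) {
  Q <- A_TAU %*% tau
  dth <- outer(th, th, "-")
  M <- cm$S * cos(dth)
  diag(M) <- diag(M) + cm$I
  # C_i = -sum_j S_ij thd_j^2 sin(th_j - th_i); element [j,i] of the matrix below
  # is S_ji thd_j^2 sin(th_j - th_i), so C = -colSums (S is symmetric)
  Cc <- -colSums(cm$S * (thd^2 * sin(dth)))
  G <- GRAV * sin(th) * cm$mr
  drop(solve(M, Q + G - Cc))
}

# Gravity-compensating joint torques at configuration th (static equilibrium).
chain_static_tau <- function(cm, th) {
  G <- GRAV * sin(th) * cm$mr
  drop(solve(A_TAU, -G))
}

# COM of the whole body (chain + static feet) relative to the ankle joint,
# plus its velocity and acceleration. Returns list of 2-vectors (y, z).
chain_com <- function(cm, th, thd, thdd = NULL) {
  u <- rbind(sin(th), cos(th))            # 2 x 3, columns u_j
  w <- rbind(cos(th), -sin(th))
  pos <- (u %*% cm$mr + cm$m_foot * cm$foot_com) / cm$m_tot
  vel <- (w %*% (cm$mr * thd)) / cm$m_tot
  acc <- if (is.null(thdd)) NULL else {
    (w %*% (cm$mr * thdd) - u %*% (cm$mr * thd^2)) / cm$m_tot
  }
  list(pos = drop(pos), vel = drop(vel), acc = if (is.null(acc)) NULL else drop(acc))
}

# Total ground reaction force (both plates) from the chain state.
chain_grf <- function(cm, th, thd, thdd) {
  acc <- chain_com(cm, th, thd, thdd)$acc
  c(Fy = cm$m_tot * acc[1L], Fz = cm$m_tot * (acc[2L] + GRAV))
}

# Centre of pressure (m, relative to the ankle, positive forward) from foot
# moment balance: 0 = tau_ankle - zA Fy - ycp Fz + ycf m_f g.
chain_cop <- function(cm, tau_ankle, Fy, Fz) {
  (tau_ankle - cm$ankle_height * Fy + cm$foot_com[1L] * cm$m_foot * GRAV) / Fz
}

# Mechanical energy of the moving chain (kinetic + gravitational, J; the
# static feet contribute a constant and are omitted).
chain_energy <- function(cm, th, thd) {
  dth <- outer(th, th, "-")
  ke <- 0.5 * sum((cm$S * cos(dth)) * outer(thd, thd)) + 0.5 * sum(cm$I * thd^2)
  pe <- GRAV * sum(cm$mr * cos(th))
  ke + pe
}

# Jacobian of the whole-body COM position w.r.t. segment angles (2 x 3).
chain_com_jacobian <- function(cm, th) {
  rbind(cos(th) * cm$mr, -sin(th) * cm$mr) / cm$m_tot
}

# One fixed-step RK4 step of the contact dynamics. State y = c(th, thd);
# tau_fun(t, th, thd) returns joint torques.
rk4_step <- function(cm, t, y, h, tau_fun) {
  f <- function(t, y) {
    th <- y[1:3]; thd <- y[4:6]
    c(thd, chain_qdd(cm, th, thd, tau_fun(t, th, thd)))
  }
  k1 <- f(t, y)
  k2 <- f(t + h / 2, y + h / 2 * k1)
  k3 <- f(t + h / 2, y + h / 2 * k2)
  k4 <- f(t + h, y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}
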