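# The chain equations of motion against independent oracles.

test_that("chain dynamics reduce to the textbook double pendulum", {
  m1 <- 3; m2 <- 1.5; L1 <- 0.8; L2 <- 0.5
  cm <- double_pendulum_chain(m1, m2, L1, L2)
  set.seed(42)
  for (i in 1:20) {
    phi <- runif(2, -2, 2)          # from downward vertical
    w <- runif(2, -4, 4)
    th <- pi - phi                  # chain angles are from upward vertical
    thd <- -w
    qdd <- jumpwork:::chain_qdd(cm, c(th, 0), c(thd, 0), c(0, 0, 0))
    oracle <- double_pendulum_acc(phi[1], phi[2], w[1], w[2], m1, m2, L1, L2)
    expect_equal(qdd[1:2], -oracle, tolerance = 1e-7)
  }
})

test_that("passive chain conserves energy and torque power balances", {
  sp <- segment_parameters(79, 1.77)
  cm <- jumpwork:::chain_model(sp)
  h <- 1 / 2000
  y <- c(0.3, -0.5, 0.2, 0.1, -0.2, 0.3)
  E0 <- jumpwork:::chain_energy(cm, y[1:3], y[4:6])
  zero_tau <- function(t, th, thd) c(0, 0, 0)
  for (i in 1:1000) y <- jumpwork:::rk4_step(cm, i * h, y, h, zero_tau)
  expect_equal(jumpwork:::chain_energy(cm, y[1:3], y[4:6]), E0, tolerance = 1e-9)

  # with torques, dE equals the integral of joint power (extensor-positive
  # torque x extension-positive joint rate)
  tfun <- function(t, th, thd) c(20 * sin(5 * t), 50 * cos(3 * t), -40 * sin(4 * t))
  y <- c(0.3, -0.5, 0.2, 0, 0, 0)
  E0 <- jumpwork:::chain_energy(cm, y[1:3], y[4:6])
  W <- 0
  jp <- function(t, y) {
    thd <- y[4:6]
    ext <- -c(thd[1], thd[1] - thd[2], thd[3] - thd[2])
    sum(tfun(t, y[1:3], thd) * ext)
  }
  for (i in 1:2000) {
    t <- (i - 1) * h
    y2 <- jumpwork:::rk4_step(cm, t, y, h, tfun)
    W <- W + h * (jp(t, y) + jp(t + h, y2)) / 2
    y <- y2
  }
  E1 <- jumpwork:::chain_energy(cm, y[1:3], y[4:6])
  expect_equal(E1 - E0, W, tolerance = 1e-5)
})

test_that("static equilibrium: gravity-compensating torques give GRF = m g and CoP = COM", {
  sp <- segment_parameters(70, 1.70)
  cm <- jumpwork:::chain_model(sp)
  th0 <- jumpwork:::seg_from_joint(c(0.1, 0.3, 0.25))
  tau0 <- jumpwork:::chain_static_tau(cm, th0)
  qdd <- jumpwork:::chain_qdd(cm, th0, c(0, 0, 0), tau0)
  expect_equal(qdd, rep(0, 3), tolerance = 1e-10)
  grf <- jumpwork:::chain_grf(cm, th0, c(0, 0, 0), qdd)
  expect_equal(unname(grf["Fz"]), cm$m_tot * 9.81, tolerance = 1e-10)
  com <- jumpwork:::chain_com(cm, th0, c(0, 0, 0))
  cop <- jumpwork:::chain_cop(cm, tau0[1], grf["Fy"], grf["Fz"])
  expect_equal(unname(cop), com$pos[1], tolerance = 1e-10)
})
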