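test_that("static standing: ankle moment equals the GRF moment about the ankle", {
  tr <- get_trial("CMJ")
  kin <- inverse_dynamics_planar(tr, filter_cutoff = NULL)
  sp <- tr$truth$segparams
  cm <- jumpwork:::chain_model(sp)
  # quiet phase: CoP sits under the whole-body COM at offset d from the ankle
  th0 <- tr$truth$state$values[1, 1:3]
  d <- jumpwork:::chain_com(cm, th0, c(0, 0, 0))$pos[1]
  m <- tr$subject$body_mass
  fz_side <- m * 9.81 / 2
  # closed form per side: GRF moment minus the foot-weight moment
  expected <- (fz_side * d - sp$foot_com_y * sp$foot$m * 9.81) / m
  got <- mean(kin$l$moment$values[50:200, "ankle"])
  expect_equal(got, expected, tolerance = 0.01)
  # and the simple Fz*d form is right to ~10% (foot weight is the remainder)
  expect_equal(got, fz_side * d / m, tolerance = 0.1)
})

test_that("inverse dynamics recovers simulator truth torques within 2% of peak", {
  # acceptance-level invariant; exercised here on two jump types, the full
  # six-type sweep lives in the acceptance suite
  for (jt in c("CMJ", "DJ60")) {
    tr <- get_trial(jt)
    kin <- inverse_dynamics_planar(tr, filter_cutoff = NULL)
    ev <- detect_events(tr)
    tt <- kin$l$moment$t
    sel <- which(tt >= ev$window[1] & tt <= ev$window[2])
    m <- tr$subject$body_mass
    for (side in c("l", "r")) {
      for (j in c("ankle", "knee", "hip")) {
        est <- kin[[side]]$moment$values[sel, j] * m
        tru <- tr$truth$torque$values[sel, paste0(j, "_", side)]
        ok <- is.finite(tru)
        expect_lt(sqrt(mean((est[ok] - tru[ok])^2)) / max(abs(tru[ok])), 0.02)
      }
    }
  }
})

test_that("isometric phases produce no work and moment-sign flips swap labels", {
  # quiet standing: omega = 0 -> zero work despite nonzero moments
  tr <- get_trial("CMJ")
  kin <- inverse_dynamics_planar(tr, filter_cutoff = NULL)
  ev <- structure(list(window = c(0.05, 0.3)), class = "jw_events")
  jw <- joint_work(kin, ev)
  for (j in c("hip", "knee", "ankle")) {
    expect_lt(abs(jw$l[[j]]$W_net), 1e-3)
  }

  # brute-force 10-sample series: flipping the moment convention flips labels
  mo <- c(1, 2, -1, 3, -2, 1, 0.5, -0.5, 2, 1)
  om <- c(0.5, -1, 1, 2, -0.5, 1, -1, 0.3, 0.2, -2)
  t10 <- (0:9) / 10
  P <- mo * om
  w_pos <- trapz(t10, pmax(P, 0))
  w_neg <- trapz(t10, pmin(P, 0))
  Pf <- (-mo) * (-om) # flipping convention flips both moment and rate
  expect_identical(Pf, P)
  Pm <- (-mo) * om    # flipping only the moment convention swaps the labels
  expect_equal(trapz(t10, pmax(Pm, 0)), -w_neg)
  expect_equal(trapz(t10, pmin(Pm, 0)), -w_pos)
})

test_that("summed net joint work matches chain mechanical-energy change within 1%", {
  tr <- get_trial("DJ45")
  kin <- inverse_dynamics_planar(tr, filter_cutoff = NULL)
  ev <- detect_events(tr)
  jw <- joint_work(kin, ev)
  m <- tr$subject$body_mass
  w_sum <- sum(vapply(c("l", "r"), function(s) {
    sum(vapply(c("hip", "knee", "ankle"), function(j) jw[[s]][[j]]$W_net, 0))
  }, 0)) * m
  cm <- jumpwork:::chain_model(tr$truth$segparams)
  st <- tr$truth$state$values
  i0 <- round(ev$window[1] * 1000) + 1
  i1 <- round(ev$window[2] * 1000) + 1
  E <- function(i) jumpwork:::chain_energy(cm, st[i, 1:3], st[i, 4:6])
  dE <- E(i1) - E(i0)
  expect_equal(w_sum, dE, tolerance = 0.01)
})

test_that("bilateral averaging is exact arithmetic with a recomputed ratio", {
  a <- jumpwork:::new_work_summary(-2, 3, "knee")
  b <- jumpwork:::new_work_summary(-4, 5, "knee")
  avg <- bilateral_average(a, b)
  expect_equal(avg$W_neg, -3)
  expect_equal(avg$W_pos, 4)
  expect_equal(avg$W_net, 1)
  expect_equal(avg$ratio, 75)

  expect_identical(bilateral_average(a, a)[c("W_neg", "W_pos", "W_net", "ratio")],
                   a[c("W_neg", "W_pos", "W_net", "ratio")])

  # ratio of averages differs from average of ratios on asymmetric sides
  mean_ratio <- mean(c(a$ratio, b$ratio))
  expect_false(isTRUE(all.equal(avg$ratio, mean_ratio)))

  expect_error(bilateral_average(a, jumpwork:::new_work_summary(-1, 1, "hip")),
               class = "jw_argument_error")
})

test_that("weak hip capacity shifts negative-work share to the knee at high drops", {
  s <- ref_subject()
  strong <- simulate_trial(s, "DJ60", seed = 77)
  weak_hip <- simulate_trial(s, "DJ60", seed = 77,
                             actuation = list(tau_max = s$body_mass * c(4.2, 6.7, 2.0)))
  share <- function(tr) {
    kin <- inverse_dynamics_planar(tr, filter_cutoff = NULL)
    jw <- joint_work(kin, detect_events(tr))
    w <- vapply(c("hip", "knee", "ankle"),
                function(j) bilateral_average(jw$l[[j]], jw$r[[j]])$W_neg, 0)
    w[["knee"]] / sum(w)
  }
  expect_gt(share(weak_hip), share(strong))
})
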