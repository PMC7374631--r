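make_force_ts <- function(fz, rate = 1000) timeseries(fz, rate, units = "N")

static_events <- function(n, rate = 1000) {
  structure(list(t_onset = 0, t_contact = NA_real_, t_lowest = 0,
                 t_takeoff = (n - 1) / rate, window = c(0, (n - 1) / rate)),
            class = "jw_events")
}

test_that("COM kinematics: static equilibrium and free fall limits", {
  m <- 70
  n <- 1001
  ev <- static_events(n)
  st <- com_kinematics(make_force_ts(rep(m * 9.81, n)), m, ev, "CMJ")
  expect_equal(max(abs(st$a)), 0)
  expect_equal(max(abs(st$v)), 0)
  expect_equal(max(abs(st$x)), 0)

  st0 <- com_kinematics(make_force_ts(rep(0, n)), m, ev, "CMJ")
  expect_equal(st0$v, -9.81 * st0$t, tolerance = 1e-12)

  expect_error(com_kinematics(make_force_ts(rep(1, 10)), 0, ev, "CMJ"),
               class = "jw_argument_error")
})

test_that("COM velocity tracks simulator truth within 2% RMS on a noiseless DJ60", {
  tr <- get_trial("DJ60")
  ev <- detect_events(tr)
  fz <- timeseries(tr$force$values[, "fz_l"] + tr$force$values[, "fz_r"],
                   1000, units = "N")
  st <- com_kinematics(fz, tr$subject$body_mass, ev, "DJ60", 0.60)
  vt <- tr$truth$com$values[st$idx, "v"]
  expect_lt(sqrt(mean((st$v - vt)^2)) / max(abs(vt)), 0.02)
})

test_that("work decomposition: sign rules, identity and time-reversal symmetry", {
  # all-ascending loop has zero negative work
  m <- 70; n <- 501
  ev <- static_events(n)
  fz <- 500 + 200 * sin(seq(0, pi, length.out = n))
  st <- com_kinematics(make_force_ts(fz), m, ev, "CMJ")
  st$v <- abs(st$v) + 0.1          # force v >= 0
  w <- com_work(make_force_ts(fz), st, ev, m)
  expect_identical(w$W_neg, 0)
  expect_equal(w$W_net, w$W_pos)

  # decomposition identity to machine precision on a real trial
  tr <- get_trial("CMJ")
  res <- analyze_trial(tr)
  for (msr in c("com", "hip", "knee", "ankle")) {
    row <- res$rows[res$rows$measure == msr, ]
    expect_identical(row$W_net, row$W_neg + row$W_pos)
  }

  # reversing time direction swaps the magnitudes of W_neg and W_pos
  st2 <- com_kinematics(make_force_ts(fz), m, ev, "CMJ")
  w_fwd <- com_work(make_force_ts(fz), st2, ev, m)
  st_rev <- st2
  st_rev$v <- -rev(st2$v)
  fz_rev <- make_force_ts(rev(fz))
  w_rev <- com_work(fz_rev, st_rev, ev, m)
  expect_equal(w_rev$W_neg, -w_fwd$W_pos, tolerance = 1e-10)
  expect_equal(w_rev$W_pos, -w_fwd$W_neg, tolerance = 1e-10)
})

test_that("energy conservation closes on noiseless drop jumps", {
  tr <- get_trial("DJ30")
  m <- tr$subject$body_mass
  ev <- detect_events(tr)
  fz <- timeseries(tr$force$values[, "fz_l"] + tr$force$values[, "fz_r"],
                   1000, units = "N")
  st <- com_kinematics(fz, m, ev, "DJ30", 0.30)
  w <- com_work(fz, st, ev, m)
  n <- length(st$v)
  dE <- (st$v[n]^2 - st$v[1]^2) / 2 + 9.81 * (st$x[n] - st$x[1])
  expect_equal(w$W_net, dE, tolerance = 0.01)
})

test_that("work loop area equals net work (Green's theorem) and spring cycles close", {
  tr <- get_trial("CMJ")
  res <- analyze_trial(tr, list(filter = list(cutoff = NULL, order = 4),
                                com_filter = FALSE))
  area <- workloop_area(res$com$loop)
  wnet <- res$com$work$W_net
  expect_equal(area, wnet, tolerance = 0.005)

  # conservative spring cycle F = -k x has zero enclosed area
  th <- seq(0, 2 * pi, length.out = 400)
  loop <- structure(list(excursion = cos(th), drive = -3 * cos(th)),
                    class = "jw_workloop")
  expect_equal(workloop_area(loop), 0, tolerance = 1e-10)

  # single-point loop is degenerate with zero area
  pt <- structure(list(excursion = 0.1, drive = 2), class = "jw_workloop")
  expect_identical(workloop_area(pt), 0)
})

test_that("negative:positive ratio arithmetic and undefined flag", {
  expect_equal(neg_pos_ratio(-2.4, 6.5), 36.92308, tolerance = 1e-6)
  expect_identical(neg_pos_ratio(0, 5), 0)
  expect_equal(neg_pos_ratio(-6, 6), 100)
  expect_true(is.na(neg_pos_ratio(-1, 0)))
  expect_error(neg_pos_ratio(-1, -1), class = "jw_argument_error")
})
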