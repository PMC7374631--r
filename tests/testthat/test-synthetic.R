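# The cohort generator and jump simulator.

test_that("cohort generation matches requested structure and is deterministic", {
  coh <- generate_cohort(9, 12, seed = 7)
  expect_length(coh$subjects, 21)
  sexes <- vapply(coh$subjects, `[[`, "", "sex")
  expect_identical(as.integer(table(sexes)[c("M", "W")]), c(9L, 12L))
  tab <- cohort_table(coh)
  expect_true(all(tab$body_mass > 0 & tab$height > 0 & tab$squat_1rm >= 0))
  expect_equal(tab$rel_strength, tab$squat_1rm / tab$body_mass)

  # same seed twice -> identical subjects; different seed -> different
  expect_identical(cohort_table(generate_cohort(9, 12, seed = 7)), tab)
  expect_false(identical(cohort_table(generate_cohort(9, 12, seed = 8)), tab))

  # truncation at 3 SD holds across many draws
  big <- cohort_table(generate_cohort(60, 60, seed = 3))
  pf <- jumpwork:::default_strength_profile()
  for (sx in c("M", "W")) {
    d <- big[big$sex == sx, ]
    expect_true(all(abs(d$body_mass - pf[[sx]]$mass[1]) <= 3 * pf[[sx]]$mass[2]))
    expect_true(all(abs(d$height - pf[[sx]]$height[1]) <= 3 * pf[[sx]]$height[2]))
  }

  expect_length(generate_cohort(0, 0)$subjects, 0)
  expect_error(generate_cohort(-1, 5), class = "jw_argument_error")
})

test_that("CMJ quiet standing carries exactly body weight", {
  tr <- get_trial("CMJ")
  m <- tr$subject$body_mass
  fz <- tr$force$values[, "fz_l"] + tr$force$values[, "fz_r"]
  expect_lt(max(abs(fz[1:300] - m * 9.81)) / (m * 9.81), 1e-3)
})

test_that("drop-jump touchdown speed matches free fall from the drop height", {
  tr <- get_trial("DJ45")
  ic <- round(tr$truth$events$t_contact * 1000) + 1
  v_td <- unname(tr$truth$com$values[ic, "v"])
  expect_equal(v_td, -sqrt(2 * 9.81 * 0.45), tolerance = 0.01)
})

test_that("Newton consistency and flight force hold on every sampled trial", {
  for (jt in c("CMJ", "DJ15", "DJ60")) {
    tr <- get_trial(jt)
    m <- tr$subject$body_mass
    fz <- tr$force$values[, "fz_l"] + tr$force$values[, "fz_r"]
    ct <- tr$truth$contact
    a <- tr$truth$com$values[, "a"]
    expect_lt(max(abs(fz[ct] - m * (a[ct] + 9.81))) / (m * 9.81), 1e-3)
    expect_true(all(fz[!ct] == 0))
  }
})

test_that("impulse-momentum closes over the contact phase", {
  for (jt in c("CMJ", "DJ30", "DJ75")) {
    tr <- get_trial(jt)
    m <- tr$subject$body_mass
    fz <- tr$force$values[, "fz_l"] + tr$force$values[, "fz_r"]
    ct <- which(tr$truth$contact)
    tt <- tr$truth$com$t[ct]
    imp <- trapz(tt, fz[ct] - m * 9.81) / m
    dv <- unname(tr$truth$com$values[max(ct), "v"] - tr$truth$com$values[min(ct), "v"])
    expect_equal(imp, dv, tolerance = 0.02)
  }
})

test_that("simulator energy bookkeeping: joint work equals chain energy change", {
  for (jt in c("CMJ", "DJ45")) {
    tr <- get_trial(jt)
    sp <- tr$truth$segparams
    cm <- jumpwork:::chain_model(sp)
    st <- tr$truth$state$values
    tau <- tr$truth$torque$values
    i <- which(tr$truth$contact)
    tt <- tr$truth$state$t[i]
    E <- vapply(i, function(j) jumpwork:::chain_energy(cm, st[j, 1:3], st[j, 4:6]), 0)
    ext <- cbind(-st[i, "thd1"], st[i, "thd2"] - st[i, "thd1"],
                 st[i, "thd2"] - st[i, "thd3"])
    tauc <- 2 * tau[i, c("ankle_l", "knee_l", "hip_l")]
    W <- trapz(tt, rowSums(tauc * ext))
    dE <- E[length(E)] - E[1]
    expect_equal(W, dE, tolerance = 0.01)
  }
})

test_that("simulation contracts and determinism", {
  s <- ref_subject()
  expect_error(simulate_trial(s, "DJ30", drop_height = -1), class = "jw_argument_error")
  expect_error(simulate_trial(s, "CMJ", sim_rate = 500), class = "jw_argument_error")
  t1 <- simulate_trial(s, "DJ15", seed = 33)
  t2 <- simulate_trial(s, "DJ15", seed = 33)
  expect_identical(t1$force$values, t2$force$values)
  expect_identical(t1$kinematics$values, t2$kinematics$values)
  t3 <- simulate_trial(s, "DJ15", seed = 34)
  expect_false(identical(t3$force$values, t1$force$values))
})

test_that("noise injection matches its stated statistics and keeps truth intact", {
  tr <- get_trial("CMJ")
  expect_identical(add_noise(tr, 0, 0, seed = 5)$force$values, tr$force$values)
  nz <- add_noise(tr, force_sd = 5, angle_sd = 0.01, seed = 5)
  resid <- nz$force$values[, "fz_l"] - tr$force$values[, "fz_l"]
  expect_equal(sd(resid), 5, tolerance = 0.15)
  aresid <- nz$kinematics$values[, "knee_r"] - tr$kinematics$values[, "knee_r"]
  expect_equal(sd(aresid), 0.01, tolerance = 0.15)
  expect_identical(nz$truth$torque$values, tr$truth$torque$values)
  expect_identical(add_noise(tr, 5, 0.01, seed = 5)$force$values, nz$force$values)
  expect_error(add_noise(tr, -1, 0), class = "jw_argument_error")
})
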