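test_that("zero-lag Butterworth passes, blocks and preserves phase as designed", {
  rate <- 1000
  t <- (0:2999) / rate

  # DC gain is exactly 1
  const <- timeseries(rep(3.3, 500), rate)
  expect_equal(lowpass_zero_lag(const, 11)$values[, 1], rep(3.3, 500),
               tolerance = 1e-9)

  # 2 Hz tone at 11 Hz cutoff: amplitude within 1% of 1, peak shift < 1 ms
  tone2 <- timeseries(sin(2 * pi * 2 * t), rate)
  f2 <- lowpass_zero_lag(tone2, 11, order = 4)
  mid <- t > 0.5 & t < 2.5
  expect_lt(abs(max(f2$values[mid, 1]) - 1), 0.01)
  win <- which(t > 0.3 & t < 0.7)
  expect_lt(abs(win[which.max(f2$values[win, 1])] -
                  win[which.max(tone2$values[win, 1])]) / rate, 1e-3)

  # 50 Hz tone attenuated below 0.01; the analytic dual-pass order-2
  # magnitude |H|^2 = 1/(1 + (50/11)^4) bounds it
  tone50 <- timeseries(sin(2 * pi * 50 * t), rate)
  f50 <- lowpass_zero_lag(tone50, 11, order = 4)
  amp50 <- max(abs(f50$values[mid, 1]))
  expect_lt(amp50, 0.01)
  expect_equal(amp50, 1 / (1 + (50 / 11)^4), tolerance = 0.15)

  # zero-crossing times of a pure tone are unchanged within one sample
  zc <- function(x) which(diff(sign(x)) != 0)
  expect_lte(max(abs(zc(f2$values[mid, 1]) - zc(tone2$values[mid, 1]))), 1)
})

test_that("filter design matches the analytic Butterworth response", {
  d <- butter_lowpass(2, 11, 1000)
  Hmag <- function(f) {
    z <- exp(2i * pi * f / 1000)
    Mod(sum(d$b * z^-(0:2)) / sum(d$a * z^-(0:2)))
  }
  # -3 dB at the (pre-warped) cutoff, analytic magnitude elsewhere
  expect_equal(Hmag(11), 1 / sqrt(2), tolerance = 1e-3)
  # bilinear warping shifts high frequencies slightly; 5% covers it at 50 Hz
  for (f in c(2, 5, 22, 50)) {
    expect_equal(Hmag(f), 1 / sqrt(1 + (f / 11)^4), tolerance = 0.05)
  }
})

test_that("filter argument contracts", {
  ts <- timeseries(rnorm(100), 1000)
  expect_error(lowpass_zero_lag(ts, 600), class = "jw_argument_error")
  expect_error(lowpass_zero_lag(ts, 11, order = 3), class = "jw_argument_error")
})
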