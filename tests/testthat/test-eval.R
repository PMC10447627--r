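test_that("rmse_nrmse implements range-normalized RMSE", {
  actual <- c(0, 5, 10, 2, 8)
  expect_equal(rmse_nrmse(actual, actual), tibble::tibble(rmse = 0, nrmse = 0))
  # constant offset c against range R gives nrmse = 100 c / R
  m <- rmse_nrmse(actual + 2, actual)
  expect_equal(m$rmse, 2)
  expect_equal(m$nrmse, 100 * 2 / 10)
  expect_error(rmse_nrmse(1:5, rep(3, 5)), class = "sonokin_value_error")
  expect_error(rmse_nrmse(1:4, 1:5), class = "sonokin_shape_error")

  # invariance: common additive constant and common rescaling
  set.seed(1)
  a <- rnorm(200)
  p <- a + rnorm(200, sd = 0.2)
  base <- rmse_nrmse(p, a)$nrmse
  expect_equal(rmse_nrmse(p + 10, a + 10)$nrmse, base)
  expect_equal(rmse_nrmse(3 * p, 3 * a)$nrmse, base)
})

test_that("published RMSE/nRMSE pairs imply physiologically plausible ranges", {
  # range implied by the ratio oracle: R = 100 * rmse / nrmse
  implied <- function(rmse, nrmse) 100 * rmse / nrmse
  normal <- c(
    knee_pos = implied(6.0, 9.0), knee_vel = implied(60.6, 7.3),
    ankle_pos = implied(1.8, 8.3), ankle_vel = implied(27.9, 10.0)
  )
  fast <- c(
    knee_pos = implied(11.7, 15.7), knee_vel = implied(125.6, 12.6),
    ankle_pos = implied(3.4, 14.0), ankle_vel = implied(46.9, 13.1)
  )
  # knee flexion excursion during prosthetic walking: tens of degrees
  expect_gt(normal[["knee_pos"]], 50); expect_lt(normal[["knee_pos"]], 90)
  expect_gt(fast[["knee_pos"]], 50); expect_lt(fast[["knee_pos"]], 100)
  # ankle excursion: ~15-30 deg
  expect_gt(normal[["ankle_pos"]], 10); expect_lt(normal[["ankle_pos"]], 35)
  expect_gt(fast[["ankle_pos"]], 10); expect_lt(fast[["ankle_pos"]], 35)
  # velocity ranges: hundreds of deg/s, knee > ankle
  expect_gt(normal[["knee_vel"]], normal[["ankle_vel"]])
  expect_gt(fast[["knee_vel"]], fast[["ankle_vel"]])
  expect_true(all(c(normal, fast) > 0))
  # faster walking implies equal-or-larger excursions
  expect_true(all(fast >= normal * 0.9))
})

test_that("the causal Butterworth filter has unit DC gain and -3 dB at cutoff", {
  spec <- filter_spec()
  expect_equal(causal_butterworth(rep(4.2, 200), spec), rep(4.2, 200))

  # steady-state amplitude at the 7 Hz cutoff is 1/sqrt(2) within 1%
  fs <- 80; fc <- 7
  t <- (0:4799) / fs
  x <- sin(2 * pi * fc * t)
  y <- causal_butterworth(x, spec)
  ss <- y[2400:4800]
  expect_equal(max(abs(ss)), 1 / sqrt(2), tolerance = 0.01)

  expect_error(filter_spec(cutoff_hz = 40), class = "sonokin_config_error")
  expect_error(causal_butterworth(c(1, NA, 3)), class = "sonokin_value_error")
})

test_that("filter coefficients match the bilinear-transform design oracle", {
  ref <- oracle_butter2(7, 80)
  bf <- signal::butter(2, 7 / 40, type = "low")
  expect_equal(as.numeric(bf$b), ref$b, tolerance = 1e-10)
  expect_equal(as.numeric(bf$a), ref$a, tolerance = 1e-10)
  # and the applied filter reproduces the oracle's difference equation
  set.seed(2)
  x <- rnorm(50)
  y <- causal_butterworth(x)
  y_ref <- numeric(50)
  xs <- x - x[1]
  for (n in 1:50) {
    y_ref[n] <- sum(ref$b * c(xs[n], if (n > 1) xs[n - 1] else 0,
      if (n > 2) xs[n - 2] else 0)) -
      sum(ref$a[2:3] * c(if (n > 1) y_ref[n - 1] else 0,
        if (n > 2) y_ref[n - 2] else 0))
  }
  expect_equal(y, y_ref + x[1], tolerance = 1e-10)
})

test_that("estimate_delay recovers imposed shifts and phase lags", {
  set.seed(3)
  t <- (0:799) / 80
  a <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 2.5 * t)
  expect_equal(estimate_delay(a, a)$delay_ms, 0)

  shifted <- c(rep(a[1], 3), a[1:(length(a) - 3)])
  d <- estimate_delay(shifted, a)
  expect_equal(d$delay_ms, 37.5) # 3 samples at 12.5 ms
  expect_true(d$reliable)

  # analytic phase-to-time oracle: lag phi at frequency f is phi/(2 pi f)
  f <- 1.25; phi <- 0.6
  lagged <- sin(2 * pi * f * t - phi)
  pure <- sin(2 * pi * f * t)
  d2 <- estimate_delay(lagged, pure)
  expect_lt(abs(d2$delay_ms - 1000 * phi / (2 * pi * f)), 12.5)

  # uncorrelated noise is flagged unreliable
  d3 <- estimate_delay(rnorm(800), rnorm(800))
  expect_false(d3$reliable)
})

test_that("the causal 7 Hz filter introduces a small positive lag", {
  set.seed(4)
  x <- rnorm(4000)
  y <- causal_butterworth(x)
  d <- estimate_delay(y, x)
  expect_gt(d$delay_ms, 0)
  expect_lte(d$delay_ms, 25)
})

test_that("average_gait_cycle resamples strides onto a 0-100% grid", {
  # perfectly periodic signal: the mean cycle equals any single period
  period <- 40
  x <- rep(sin(2 * pi * (0:(period - 1)) / period), 6)
  events <- seq(0, 5 * period, by = period)
  cyc <- average_gait_cycle(x, events)
  expect_equal(nrow(cyc), 101)
  expect_equal(cyc$gait_pct, seq(0, 100, 1))
  one <- approx(seq(0, 100, length.out = period + 1),
    c(x[1:period], x[1]), xout = cyc$gait_pct)$y
  expect_equal(cyc$value, one, tolerance = 1e-12)

  expect_error(average_gait_cycle(x, events[1]), class = "sonokin_value_error")

  # noise averaging: pointwise deviation shrinks ~ 1/sqrt(n) across strides
  set.seed(5)
  n_strides <- 64
  clean <- rep(sin(2 * pi * (0:(period - 1)) / period), n_strides + 1)
  noisy <- clean + rnorm(length(clean), sd = 0.5)
  ev <- seq(0, n_strides * period, by = period)
  mean_cyc <- average_gait_cycle(noisy, ev)
  one_cyc <- average_gait_cycle(noisy[1:(2 * period + 1)], ev[1:3])
  truth <- approx(seq(0, 100, length.out = period + 1),
    c(clean[1:period], clean[1]), xout = mean_cyc$gait_pct)$y
  v_many <- mean((mean_cyc$value - truth)^2)
  v_two <- mean((one_cyc$value - truth)^2)
  # expect roughly (n/2)-fold variance reduction; allow a factor of 3
  expect_lt(v_many, v_two / (n_strides / 2) * 3)
})

test_that("peak_delay_ms converts gait-percent differences to milliseconds", {
  expect_identical(peak_delay_ms(8.9, 5.5, 1.2), 41L)
  expect_identical(peak_delay_ms(49.5, 46.3, 1.2), 38L)
  expect_identical(peak_delay_ms(33.3, 33.3, 1.1), 0L)
  # antisymmetry in the two timing arguments
  expect_equal(peak_delay_ms(20, 12, 1.2), -peak_delay_ms(12, 20, 1.2))
  expect_error(peak_delay_ms(120, 5, 1.2))
})

test_that("range_metrics quantifies range reduction and peak shortfall", {
  grid <- seq(0, 100, 1)
  actual <- 30 + 25 * sin(2 * pi * grid / 100)
  m0 <- range_metrics(actual, actual)
  expect_equal(m0$range_ratio, 100)
  expect_equal(m0$peak_shortfall, 0)

  # zero-baseline linear scaling: ratio equals the scale
  zb <- 25 * sin(2 * pi * grid / 100)
  m1 <- range_metrics(0.913 * zb, zb)
  expect_equal(m1$range_ratio, 91.3)

  # peak shortfall of 2% when the predicted peak is 98% of the actual
  m2 <- range_metrics(0.98 * actual, actual, extremum = "max")
  expect_equal(m2$peak_shortfall, 2.0, tolerance = 1e-9)
  # named minimum works too (e.g. peak plantarflexion)
  m3 <- range_metrics(0.98 * zb, zb, extremum = "min")
  expect_equal(m3$peak_shortfall, 2.0, tolerance = 1e-9)

  expect_error(range_metrics(zb, rep(0, 101)), class = "sonokin_value_error")
  expect_error(range_metrics(zb[1:50], zb), class = "sonokin_shape_error")
})
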