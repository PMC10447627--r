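test_that("gait profiles are seeded, class-specific, and reject unknown classes", {
  p1 <- make_gait_profile("normal", seed = 1)
  p2 <- make_gait_profile("normal", seed = 1)
  expect_identical(p1, p2)

  pf <- make_gait_profile("fast", seed = 1)
  expect_equal(pf$stride_time_mean, 1.0)
  expect_equal(pf$stride_time_sd, 0.2)
  expect_equal(p1$stride_time_mean, 1.2)
  expect_equal(p1$stride_time_sd, 0.1)
  # same seed => same subject: harmonic phases shared across speed classes
  expect_equal(pf$fourier$knee_pos$phase, p1$fourier$knee_pos$phase)

  expect_error(make_gait_profile("jog", seed = 1), class = "sonokin_config_error")
})

test_that("sampled stride times match the class moments (Monte Carlo)", {
  set.seed(42)
  tn <- sample_stride_times(make_gait_profile("normal", 1), 10000)
  tf <- sample_stride_times(make_gait_profile("fast", 1), 10000)
  # mean within 3 standard errors of 1.2 s
  expect_lt(abs(mean(tn) - 1.2), 3 * 0.1 / sqrt(10000))
  # sd of the fast class ~= 0.2 s (sample-sd oracle; se(sd) ~ sd/sqrt(2n))
  expect_lt(abs(sd(tf) - 0.2), 4 * 0.2 / sqrt(2 * 10000))
  expect_true(all(tn > 0) && all(tf > 0))
})

test_that("kinematics are periodic with analytic velocities", {
  p <- make_gait_profile("normal", seed = 3)
  eps <- 1e-9
  k0 <- kinematics_at(p, 0)
  k1 <- kinematics_at(p, 1 - eps)
  expect_equal(k0$knee_pos, k1$knee_pos, tolerance = 1e-6)
  expect_equal(k0$ankle_vel, k1$ankle_vel, tolerance = 1e-4)

  # single-harmonic profile has position range exactly 2A
  p1h <- p
  p1h$fourier$knee_pos <- tibble::tibble(harmonic = 1, amplitude = 7, phase = 0.4)
  grid <- seq(0, 1, length.out = 4001)
  pos <- kinematics_at(p1h, grid)$knee_pos
  expect_equal(diff(range(pos)), 14, tolerance = 1e-5)

  # velocity equals the central finite difference of position over phase
  h <- 1e-5
  kin <- kinematics_at(p, grid, stride_time = 1.2)
  fd <- (kinematics_at(p, grid + h, 1.2)$knee_pos -
    kinematics_at(p, grid - h, 1.2)$knee_pos) / (2 * h) / 1.2
  expect_lt(max(abs(kin$knee_vel - fd)), 1e-4)
  fd_a <- (kinematics_at(p, grid + h, 1.2)$ankle_pos -
    kinematics_at(p, grid - h, 1.2)$ankle_pos) / (2 * h) / 1.2
  expect_lt(max(abs(kin$ankle_vel - fd_a)), 1e-4)
})

test_that("synthetic frames have 997 samples and deterministic noise-free content", {
  prof <- make_gait_profile("normal", 2)
  echo <- make_echo_model(prof, 2, noise_sd = 0)
  f1 <- synth_raw_frame(echo, 1, 0.3, prof)
  f2 <- synth_raw_frame(echo, 1, 0.3, prof)
  expect_length(f1, 997)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))

  # all modulated depths stay inside the 3.94 cm span by construction
  r <- echo$reflectors
  expect_true(all(r$depth_cm - echo$mod_amp_cm >= 0))
  expect_true(all(r$depth_cm + echo$mod_amp_cm <= 3.94))
})

test_that("echo peaks track the coupled joint variable monotonically", {
  prof <- make_gait_profile("normal", 4)
  echo <- make_echo_model(prof, 4, noise_sd = 0)
  cm_per_sample <- 3.94 / 997
  r <- echo$reflectors
  # pick the knee-position reflector of channel 1 and isolate it
  i <- which(r$channel == 1 & r$variable == "knee_pos")[1]
  echo$reflectors <- r[i, ]
  phases <- seq(0, 0.99, by = 0.01)
  centers <- purrr::map_dbl(phases, function(ph) {
    which.max(synth_raw_frame(echo, 1, ph, prof))
  })
  f <- pmin(1, pmax(-1, (kinematics_at(prof, phases)$knee_pos -
    echo$norms$knee_pos$center) / echo$norms$knee_pos$halfrange))
  ord <- order(f)
  moved <- centers[ord]
  expected_dir <- echo$reflectors$coupling_sign[1]
  expect_true(all(diff(moved) * expected_dir >= 0))
  # displacement amplitude matches the configured modulation (peak-finding
  # oracle: argmax within one sample of the analytic center)
  analytic <- (echo$reflectors$depth_cm +
    echo$mod_amp_cm * expected_dir * f) / cm_per_sample
  expect_lt(max(abs(centers - analytic)), 1.5)
})

test_that("simulated trials obey the round-robin acquisition law", {
  trial <- tiny_session(seed = 7, duration_s = 6)
  expect_equal(nrow(trial$frames), 480) # 6 s x 80 Hz
  expect_identical(trial$channel[1:8], rep(1:4, 2))
  expect_identical(
    trial$channel,
    as.integer((trial$kinematics$tick %% 4) + 1)
  )
  # one full refresh of a channel spans 4 ticks = 50 ms
  expect_identical(unique(diff(which(trial$channel == 2))), 4L)

  # stride events: strictly increasing, count ~ duration / stride time
  expect_true(all(diff(trial$stride_events) > 0))
  n_expected <- 6 / 1.2
  expect_lte(abs(length(trial$stride_events) - n_expected), 2)

  # re-simulation with the same seed is bit-identical
  trial2 <- tiny_session(seed = 7, duration_s = 6)
  expect_identical(trial$frames, trial2$frames)
  expect_identical(trial$kinematics, trial2$kinematics)

  expect_error(
    simulate_trial(make_gait_profile("normal", 1),
      make_echo_model(make_gait_profile("normal", 1), 1), -2),
    class = "sonokin_config_error"
  )
})

test_that("trial velocity streams match finite differences of positions", {
  trial <- tiny_session(seed = 11, duration_s = 6)
  kin <- trial$kinematics
  # central differences in time, away from stride boundaries where the
  # phase rate jumps between strides
  fd <- (kin$knee_pos[3:nrow(kin)] - kin$knee_pos[1:(nrow(kin) - 2)]) * 80 / 2
  mid <- 2:(nrow(kin) - 1)
  near_event <- mid %in% c(
    trial$stride_events, trial$stride_events + 1, trial$stride_events + 2
  )
  err <- abs(kin$knee_vel[mid] - fd)[!near_event]
  # finite-difference truncation error bound: |f'''| h^2 / 6, generous
  expect_lt(stats::quantile(err, 0.95), 0.05 * max(abs(kin$knee_vel)))
})
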