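# Synthetic RF generator: trajectories, surface motion, A-scans, datasets.

test_that("trajectory schedules follow the logistic transition", {
  traj <- coagulation_trajectory(f_liquid = 100, f_solid = 300,
                                 t_mid = 120, width = 10, lag = 60)
  # logistic midpoint
  expect_equal(trajectory_frequency(traj, 120), 200)
  # frozen liquid state during the lag phase
  expect_equal(trajectory_frequency(traj, c(0, 30, 59.9)), rep(100, 3))
  # analytic logistic tail bound
  expect_lt(abs(trajectory_frequency(traj, 120 + 10 * 10 + 1) - 300),
            1e-4 * 200)
  # constant trace when the endpoints coincide
  flat <- flat_trajectory(f = 150)
  expect_equal(trajectory_frequency(flat, c(0, 100, 1000)), rep(150, 3))
  # amplitude falls, damping rises, along the same schedule
  expect_equal(trajectory_amplitude(traj, 120), (5e-6 + 0.5e-6) / 2)
  expect_equal(trajectory_damping(traj, 120), (20 + 150) / 2)
})

test_that("trajectory frequency is monotone non-decreasing (property)", {
  set.seed(42)
  for (i in 1:50) {
    f0 <- runif(1, 20, 200)
    traj <- coagulation_trajectory(
      f_liquid = f0, f_solid = f0 + runif(1, 0, 400),
      t_mid = runif(1, 60, 900), width = runif(1, 1, 60),
      lag = runif(1, 0, 300))
    t <- sort(runif(200, 0, 2000))
    expect_true(all(diff(trajectory_frequency(traj, t)) >= 0))
  }
})

test_that("surface motion is a damped harmonic oscillation", {
  seqq <- short_sequence()
  traj <- flat_trajectory(f = 200, a = 5e-6, beta = 20)
  s <- surface_motion(traj, 0, seqq)
  expect_length(s, seqq$n_detection)
  expect_identical(s[1], 0)  # sine phase at tau = 0
  tau <- (seq_along(s) - 1) / seqq$detection_prf
  # closed-form envelope: at tau = 1/beta the envelope is A/e
  expect_equal(s, 5e-6 * exp(-20 * tau) * sin(2 * pi * 200 * tau),
               tolerance = 1e-12)
  i <- which.min(abs(tau - 1 / 20))
  expect_lte(abs(s[i]), 5e-6 / exp(1) + 1e-12)
  zero <- coagulation_trajectory(a_liquid = 0, a_solid = 0)
  expect_true(all(surface_motion(zero, 0, seqq) == 0))
})

test_that("A-scan echoes sit at the planted delays", {
  g <- well_geometry()
  seqq <- short_sequence()
  em <- echo_model()
  a0 <- synthesize_ascan(0, g, seqq, em)
  # surface echo centred at the nominal delay: envelope peak at t0
  env <- Mod(analytic_signal(a0$samples))
  late <- seq(round(2e-6 * seqq$sampling_rate), length(env))
  t_pk <- (late[which.max(env[late])] - 1) / seqq$sampling_rate
  expect_lt(abs(t_pk - em$surface_delay), 1 / seqq$sampling_rate)

  # 10 um displacement shifts the echo by 2 * 10e-6 / 1480 = 13.51 ns
  a1 <- synthesize_ascan(10e-6, g, seqq, em)
  d <- estimate_delay(a1$samples, a0$samples,
                      window = echo_window(2e-6, 2e-6),
                      sampling_rate = seqq$sampling_rate)
  expect_equal(d$delay, 2 * 10e-6 / 1480, tolerance = 0.05)
  expect_gt(d$quality, 0.99)

  # aliasing guard
  bad <- pulse_sequence(sampling_rate = 15e6, carrier_frequency = 5e6,
                        total_duration = 6)
  expect_error(synthesize_ascan(0, g, bad, em), "aliasing")
})

test_that("channel simulation is deterministic and carries its truth", {
  seqq <- short_sequence()
  traj <- coagulation_trajectory()
  ch1 <- simulate_channel(traj, seqq, seed = 11)
  ch2 <- simulate_channel(traj, seqq, seed = 11)
  ch3 <- simulate_channel(traj, seqq, seed = 12)
  expect_length(ch1$measurements, 10L)  # 60 s / 6 s
  expect_identical(ch1$measurements, ch2$measurements)
  expect_false(identical(ch1$measurements[[1]]$detection,
                         ch3$measurements[[1]]$detection))
  expect_identical(ch1$truth, traj)
  expect_identical(dim(ch1$measurements[[1]]$baseline)[1], 20L)
  expect_identical(dim(ch1$measurements[[1]]$detection)[1],
                   seqq$n_detection)
  # simulation must not perturb the session RNG
  set.seed(99); before <- .Random.seed
  invisible(simulate_channel(traj, seqq, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("plate simulation synchronizes channels with independent noise", {
  seqq <- pulse_sequence(total_duration = 12, n_detection = 64)
  traj <- coagulation_trajectory()
  # noise off, identical trajectories -> identical channels
  p0 <- simulate_plate(rep(list(traj), 4), seqq, noise_snr_db = Inf, seed = 3)
  expect_length(p0$channels, 4L)
  expect_identical(p0$channels[[1]]$measurements,
                   p0$channels[[4]]$measurements)
  # noise on -> distinct noise streams
  p1 <- simulate_plate(rep(list(traj), 4), seqq, noise_snr_db = 30, seed = 3)
  expect_false(identical(p1$channels[[1]]$measurements[[1]]$detection,
                         p1$channels[[2]]$measurements[[1]]$detection))
  # staggered transition midpoints preserved in channel order
  mids <- c(90, 180, 360, 600)
  trajs <- lapply(mids, function(tm)
    coagulation_trajectory(t_mid = tm, lag = 60))
  p2 <- simulate_plate(trajs, seqq, noise_snr_db = Inf, seed = 3)
  expect_equal(vapply(p2$channels, function(ch) ch$truth$t_mid, numeric(1)),
               mids)
})

test_that("planted echo delays are exact with noise disabled", {
  # tracked delay of noise-free scans equals t0 + 2S/c to well within one
  # sixteenth of a sampling interval
  g <- well_geometry()
  seqq <- short_sequence(n_detection = 32)
  traj <- flat_trajectory(f = 200, a = 5e-6, beta = 20)
  ch <- simulate_channel(traj, seqq, noise_snr_db = Inf, seed = 1)
  tr <- track_measurement(ch$measurements[[1]], geometry = g, seq = seqq)
  s_true <- surface_motion(traj, 0, seqq)[1:32]
  delay_err <- 2 * abs(tr$values - s_true) / g$sound_speed
  expect_lt(max(delay_err), 1 / (16 * seqq$sampling_rate))
})
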