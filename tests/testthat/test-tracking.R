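# Cross-correlation displacement tracking.

test_that("baseline template averages scans and suppresses noise", {
  x <- sin(2 * pi * (0:63) / 8)
  expect_identical(baseline_template(rbind(x, x, x)), x)
  expect_identical(baseline_template(x), x)
  expect_error(baseline_template(matrix(numeric(0), 0, 8)), "no baseline")
  expect_error(baseline_template(list(1:4, 1:5)), "mismatched")

  # Monte-Carlo oracle: variance of a 20-scan mean is sigma^2 / 20
  set.seed(7)
  sigma <- 0.5
  pooled <- replicate(100, {
    b <- matrix(rnorm(20 * 64, sd = sigma), nrow = 20)
    baseline_template(b)
  })
  expect_equal(var(as.vector(pooled)), sigma^2 / 20, tolerance = 0.3)
})

test_that("FFT correlation equals the brute-force oracle at every lag", {
  set.seed(1)
  for (i in 1:10) {
    L <- sample(32:512, 1)
    x <- rnorm(L)
    y <- rnorm(L)
    got <- normalized_xcorr(x, y, max_lag = 16)
    want <- brute_force_nxc(x, y, max_lag = 16)
    expect_equal(got$lags, want$lags)
    expect_equal(got$r, want$r, tolerance = 1e-9)
  }
})

test_that("delay estimation recovers integer and sub-sample shifts", {
  g <- well_geometry()
  seqq <- short_sequence()
  em <- echo_model()
  fs <- seqq$sampling_rate
  template <- synthesize_ascan(0, g, seqq, em)$samples

  # self-correlation: zero delay, perfect quality
  d0 <- estimate_delay(template, template, sampling_rate = fs)
  expect_equal(d0$delay, 0)
  expect_equal(d0$quality, 1, tolerance = 1e-12)
  expect_false(d0$low_quality)

  # exact integer shift by padding
  shifted <- c(numeric(3), template[1:(length(template) - 3)])
  d3 <- estimate_delay(shifted, template, sampling_rate = fs)
  expect_equal(d3$delay, 3 / fs, tolerance = 0.02)

  # analytic sub-sample placement: 0.30-sample shift
  s <- 0.30 / fs * g$sound_speed / 2
  scan <- synthesize_ascan(s, g, seqq, em)$samples
  dss <- estimate_delay(scan, template, window = echo_window(2e-6, 2e-6),
                        sampling_rate = fs)
  expect_lt(abs(dss$delay - 0.30 / fs) * fs, 0.05)

  # uncorrelated noise flags low quality without raising
  set.seed(2)
  junk <- rnorm(length(template))
  dj <- estimate_delay(junk, template, sampling_rate = fs)
  expect_true(dj$low_quality)
})

test_that("sub-sample shift estimation is unbiased at 30 dB SNR (property)", {
  g <- well_geometry()
  seqq <- short_sequence()
  em <- echo_model()
  fs <- seqq$sampling_rate
  noise_sd <- 10^(-30 / 20)
  win <- echo_window(2e-6, 2e-6)
  set.seed(123)
  template <- synthesize_ascan(0, g, seqq, em)$samples
  shifts <- runif(200, -0.5, 0.5)
  errs <- vapply(shifts, function(sh) {
    s <- sh / fs * g$sound_speed / 2
    scan <- synthesize_ascan(s, g, seqq, em)$samples +
      rnorm(length(template), sd = noise_sd)
    d <- estimate_delay(scan, template, window = win, sampling_rate = fs)
    (d$delay * fs) - sh
  }, numeric(1))
  expect_lte(mean(abs(errs)), 0.05)
})

test_that("delay-to-displacement conversion is the half round trip", {
  g <- well_geometry()
  expect_equal(delay_to_displacement(0, g), 0)
  expect_equal(delay_to_displacement(13.514e-9, g), 10e-6, tolerance = 1e-3)
  expect_equal(delay_to_displacement(2 * 3e-9, g),
               2 * delay_to_displacement(3e-9, g))
})

test_that("tracked traces recover planted motion", {
  g <- well_geometry()
  seqq <- short_sequence()
  # zero-displacement, noise-free: sub-nanometre residuals
  still <- coagulation_trajectory(a_liquid = 0, a_solid = 0)
  ch0 <- simulate_channel(still, seqq, noise_snr_db = Inf, seed = 4)
  tr0 <- track_measurement(ch0$measurements[[1]], geometry = g, seq = seqq)
  expect_length(tr0$values, seqq$n_detection)
  expect_lt(max(abs(tr0$values)), 1e-9)
  expect_true(all(tr0$quality > 0.99))

  # noise-free damped oscillator: errors bounded by a sixteenth of the
  # sampling grid in delay units
  traj <- flat_trajectory(f = 200, a = 5e-6, beta = 20)
  ch <- simulate_channel(traj, seqq, noise_snr_db = Inf, seed = 4)
  tr <- track_measurement(ch$measurements[[1]], geometry = g, seq = seqq)
  s_true <- surface_motion(traj, 0, seqq)
  expect_lt(max(abs(tr$values - s_true)),
            g$sound_speed / (2 * 16 * seqq$sampling_rate))
})

test_that("displacement matrices stack traces with gap handling", {
  g <- well_geometry()
  seqq <- short_sequence(n_detection = 64)
  traj <- coagulation_trajectory()
  ch <- simulate_channel(traj, seqq, noise_snr_db = Inf, seed = 6)
  dm <- build_matrix(ch)
  expect_identical(dim(dm$matrix), c(10L, 64L))
  expect_equal(dm$slow_times, seq(0, 54, by = 6))
  # row m is exactly the per-measurement trace
  tr3 <- track_measurement(ch$measurements[[3]],
                           window = locate_echo_window(
                             baseline_template(ch$measurements[[1]]$baseline),
                             seqq$sampling_rate),
                           geometry = g, seq = seqq)
  expect_equal(dm$matrix[3, ], tr3$values)
  # a missing measurement becomes an NA gap row, matrix stays rectangular
  ch$measurements[5] <- list(NULL)
  dm2 <- build_matrix(ch)
  expect_identical(dim(dm2$matrix), c(10L, 64L))
  expect_true(all(is.na(dm2$matrix[5, ])))
  expect_false(anyNA(dm2$matrix[-5, ]))
})
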