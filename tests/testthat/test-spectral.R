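# Power spectra, spectrograms, peak tracking, damping.

test_that("power spectrum satisfies Parseval and locates exact-bin tones", {
  dt <- 1e-4
  n <- 500
  tau <- (0:(n - 1)) * dt
  x <- 3e-6 * exp(-20 * tau) * sin(2 * pi * 200 * tau)
  ps1 <- power_spectrum(x, pad_factor = 1, fast_time_step = dt)
  xm <- x - mean(x)
  expect_equal(sum(ps1$power), sum(xm^2), tolerance = 1e-6)

  # undamped tone on an exact bin: DFT identity (unpadded transform, where
  # every off-tone bin is numerically zero)
  f0 <- 200  # = 10 bins of 20 Hz
  y <- sin(2 * pi * f0 * tau)
  ps <- power_spectrum(y, pad_factor = 1, fast_time_step = dt)
  expect_true(ps$valid)
  expect_equal(ps$peak_frequency, f0, tolerance = 1e-6)

  # degenerate traces give the invalid sentinel, not an error
  expect_false(power_spectrum(numeric(500), fast_time_step = dt)$valid)
  expect_false(power_spectrum(rep(2.5, 500), fast_time_step = dt)$valid)
})

test_that("peak error stays within one unpadded bin for damped tones", {
  dt <- 1e-4
  n <- 500
  tau <- (0:(n - 1)) * dt
  res <- 1 / (n * dt)  # 20 Hz
  for (f in c(50, 120, 200, 555, 1000, 2000)) {
    y <- exp(-20 * tau) * sin(2 * pi * f * tau)
    ps <- power_spectrum(y, pad_factor = 8, fast_time_step = dt)
    expect_lt(abs(ps$peak_frequency - f), res)
  }
})

test_that("spectral FWHM increases strictly with planted damping", {
  dt <- 1e-4
  tau <- (0:499) * dt
  widths <- vapply(c(20, 40, 80, 150, 300), function(b) {
    ps <- power_spectrum(exp(-b * tau) * sin(2 * pi * 500 * tau),
                         pad_factor = 8, fast_time_step = dt)
    ps$peak_width_fwhm
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("spectrogram columns are unit-normalized with masked gaps", {
  seqq <- short_sequence(n_detection = 256)
  dt <- 1 / seqq$detection_prf
  traj <- flat_trajectory(f = 200)
  traces <- lapply(1:8, function(m) surface_motion(traj, (m - 1) * 6, seqq))
  traces[[4]] <- rep(0, seqq$n_detection)  # degenerate measurement
  dm <- matrix_from_traces(traces, dt)
  sg <- rar_spectrogram(dm)
  expect_false(sg$valid[4])
  expect_true(all(is.na(sg$normalized_power[, 4])))
  for (m in which(sg$valid))
    expect_equal(max(sg$normalized_power[, m]), 1)
  # constant trajectory: tracked peak constant within one unpadded bin
  pk <- sg$peak_series[sg$valid]
  expect_lt(max(pk) - min(pk), 1 / (seqq$n_detection * dt))
})

test_that("a frequency step produces exactly one upward peak transition", {
  seqq <- short_sequence(n_detection = 256)
  dt <- 1 / seqq$detection_prf
  lowf <- flat_trajectory(f = 100)
  highf <- flat_trajectory(f = 300)
  traces <- c(lapply(1:6, function(m) surface_motion(lowf, 0, seqq)),
              lapply(1:6, function(m) surface_motion(highf, 0, seqq)))
  sg <- rar_spectrogram(matrix_from_traces(traces, dt))
  bin <- 1 / (seqq$n_detection * dt)
  jumps <- which(abs(diff(sg$peak_series)) > 2 * bin)
  expect_identical(jumps, 6L)
  expect_gt(sg$peak_series[7] - sg$peak_series[6], 0)
})

test_that("peak tracking median-filters outliers and interpolates gaps", {
  seqq <- short_sequence(n_detection = 256)
  dt <- 1 / seqq$detection_prf
  traj <- flat_trajectory(f = 200)
  traces <- lapply(1:9, function(m) surface_motion(traj, 0, seqq))
  traces[[5]] <- surface_motion(flat_trajectory(f = 800), 0, seqq)  # outlier
  traces[[7]] <- rep(0, seqq$n_detection)                           # gap
  sg <- rar_spectrogram(matrix_from_traces(traces, dt))
  series <- track_peak(sg, smooth_window = 3)
  expect_s3_class(series, "rar_freq_series")
  expect_true(series$interpolated[7])
  # the single-column outlier is removed by the window-3 median
  expect_lt(max(abs(series$frequency - 200)), 1 / (seqq$n_detection * dt))
  # an already-smooth series passes through unchanged
  sg2 <- rar_spectrogram(matrix_from_traces(traces[1:4], dt))
  expect_equal(track_peak(sg2, smooth_window = 3)$frequency,
               sg2$peak_series)
  # too few valid columns is an error
  sg_bad <- sg
  sg_bad$valid[] <- FALSE
  sg_bad$valid[1:2] <- TRUE
  expect_error(track_peak(sg_bad), "at least 3")
})

test_that("damping estimation recovers planted decay rates", {
  dt <- 1e-4
  n <- 500
  tau <- (0:(n - 1)) * dt
  # undamped tone: estimate indistinguishable from zero
  expect_lt(abs(estimate_damping(sin(2 * pi * 200 * tau),
                                 fast_time_step = dt)), 1 / (10 * n * dt))
  # planted beta = 40, noise off: within 5%
  y40 <- exp(-40 * tau) * sin(2 * pi * 200 * tau)
  expect_equal(estimate_damping(y40, fast_time_step = dt), 40,
               tolerance = 0.05)
  # strict ordering of estimates with planted damping
  ests <- vapply(c(40, 80, 150), function(b)
    estimate_damping(exp(-b * tau) * sin(2 * pi * 200 * tau),
                     fast_time_step = dt), numeric(1))
  expect_true(all(diff(ests) > 0))
  # non-oscillatory input: no-estimate sentinel
  expect_true(is.na(estimate_damping(exp(-30 * tau), fast_time_step = dt)))
  expect_true(is.na(estimate_damping(numeric(n), fast_time_step = dt)))
})

test_that("envelope damping agrees with the spectral line width when the
          line dominates the window", {
  dt <- 1e-4
  n <- 5000  # long window so the Lorentzian width exceeds the mainlobe
  tau <- (0:(n - 1)) * dt
  for (bT in c(3, 5)) {
    b <- bT / (n * dt)
    y <- exp(-b * tau) * sin(2 * pi * 200 * tau)
    ps <- power_spectrum(y, pad_factor = 8, fast_time_step = dt)
    be <- estimate_damping(y, fast_time_step = dt)
    expect_equal(pi * ps$peak_width_fwhm, be, tolerance = 0.25)
  }
})
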