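# Coagulation-parameter extraction from frequency series.

series_df <- function(time, frequency) {
  structure(data.frame(time = time, frequency = frequency,
                       interpolated = FALSE),
            class = c("rar_freq_series", "data.frame"))
}

test_that("initial and final frequency windows are boundary-inclusive", {
  t6 <- seq(0, 594, by = 6)
  expect_equal(f_initial(series_df(t6, rep(100, length(t6)))), 100)
  # window isolation: only the first minute enters f_int
  f <- ifelse(t6 <= 60, 90, 300)
  expect_equal(f_initial(series_df(t6, f)), 90)
  # exactly the 11 grid points T = 0, 6, ..., 60 are averaged
  f_idx <- seq_along(t6)
  expect_equal(f_initial(series_df(t6, f_idx)), mean(1:11))

  t_full <- seq(0, 3594, by = 6)  # 600 rows of a 3600 s run
  expect_equal(f_final(series_df(t_full, rep(250, length(t_full)))), 250)
  fl <- ifelse(t_full >= max(t_full) - 300, 400, 100)
  expect_equal(f_final(series_df(t_full, fl)), 400)
  # boundary-inclusive: 51 samples in the closing 5-minute window
  expect_equal(sum(t_full >= max(t_full) - 300), 51L)
  expect_equal(f_final(series_df(t_full, seq_along(t_full))),
               mean(550:600))

  expect_error(f_initial(series_df(seq(0, 54, 6), rep(1, 10))), "60 s")
  expect_error(f_final(series_df(seq(0, 294, 6), rep(1, 50))), "5 min")
})

test_that("clotting start and end follow the sustained threshold rules", {
  t6 <- seq(0, 3594, by = 6)
  # constant series never rises: no-clot sentinel
  expect_true(is.na(clotting_start(series_df(t6, rep(100, 600)), 100)))
  # step 100 -> 300 Hz at T = 90 s
  f_step <- ifelse(t6 < 90, 100, 300)
  expect_equal(clotting_start(series_df(t6, f_step), 100), 90)
  expect_equal(clotting_end(series_df(t6, f_step), 300), 90)
  # constant series reaches 95% of f_end at the first sample (degenerate)
  expect_equal(clotting_end(series_df(t6, rep(100, 600)), 100), 0)
  # linear ramp: earliest grid point with f >= 105, verified by scan
  t_r <- seq(0, 600, by = 6)
  f_r <- 100 + (200 - 100) * t_r / 600
  got <- clotting_start(series_df(t_r, f_r), 100)
  expect_equal(got, t_r[which(f_r >= 105)[1]])
  # a single-sample spike must not trigger the sustained rule
  f_spike <- rep(100, 600)
  f_spike[50] <- 200
  expect_true(is.na(clotting_start(series_df(t6, f_spike), 100)))
})

test_that("threshold rules agree exactly with the exhaustive scan (property)", {
  set.seed(31)
  t6 <- seq(0, 1194, by = 6)
  for (i in 1:1000) {
    # random piecewise-monotone series: lag, ramp, plateau + jitter
    f0 <- runif(1, 50, 150)
    f1 <- f0 * runif(1, 1.0, 4.0)
    lag <- sample(seq_along(t6), 1)
    rise <- sample(1:60, 1)
    f <- c(rep(f0, lag),
           seq(f0, f1, length.out = rise),
           rep(f1, length(t6)))[seq_along(t6)]
    f <- f + rnorm(length(f), sd = runif(1, 0, 3))
    thr_s <- 1.05 * f0
    thr_e <- 0.95 * f1
    s <- series_df(t6, f)
    expect_identical(clotting_start(s, f0), brute_force_crossing(t6, f, thr_s))
    expect_identical(clotting_end(s, f1), brute_force_crossing(t6, f, thr_e))
  }
})

test_that("parameter extraction composes the rules with sentinels", {
  g <- well_geometry()
  t6 <- seq(0, 3594, by = 6)
  f_step <- ifelse(t6 < 90, 100, 300)
  p <- extract_parameters(series_df(t6, f_step), g)
  expect_true(p$clot_detected)
  expect_equal(p$f_int, 100)
  expect_equal(p$f_end, 300)
  expect_equal(p$T_int, 90)
  expect_equal(p$T_end, 90)
  expect_equal(p$duration, 0)
  expect_equal(p$final_shear_modulus, invert_shear_modulus(300, g))

  # flat liquid trace: sentinels, no modulus, no error
  pf <- extract_parameters(series_df(t6, rep(100, 600)), g)
  expect_false(pf$clot_detected)
  expect_true(is.na(pf$T_int))
  expect_true(is.na(pf$duration))
  expect_true(is.na(pf$final_shear_modulus))

  # order invariant on a logistic trajectory
  traj <- coagulation_trajectory(t_mid = 150, width = 20, lag = 60)
  f_log <- trajectory_frequency(traj, t6)
  pl <- extract_parameters(series_df(t6, f_log), g)
  expect_true(pl$clot_detected)
  expect_lte(pl$T_int, pl$T_end)
  expect_gte(pl$duration, 0)
  expect_gt(pl$f_end, pl$f_int)

  # optional dead-time offset shifts reported times only
  po <- extract_parameters(series_df(t6, f_step), g, time_offset = 87)
  expect_equal(po$T_int, 90 + 87)
  expect_equal(po$duration, p$duration)
})

test_that("stiffer planted endpoints yield larger final moduli", {
  g <- well_geometry()
  t6 <- seq(0, 1194, by = 6)
  moduli <- vapply(c(200, 300, 450), function(fs) {
    traj <- coagulation_trajectory(f_solid = fs, t_mid = 150, width = 20,
                                   lag = 60)
    p <- extract_parameters(series_df(t6, trajectory_frequency(traj, t6)), g)
    p$final_shear_modulus
  }, numeric(1))
  expect_true(all(diff(moduli) > 0))
})

test_that("parameter tables are tidy one-row-per-channel exports", {
  g <- well_geometry()
  t6 <- seq(0, 594, by = 6)
  p1 <- extract_parameters(series_df(t6, ifelse(t6 < 90, 100, 300)), g)
  p2 <- extract_parameters(series_df(t6, rep(100, length(t6))), g)
  tab <- parameters_table(list(p1, p2), config_hash = "abc123")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$channel, c(1L, 2L))
  expect_identical(tab$clot_detected, c(TRUE, FALSE))
  expect_identical(tab$config_hash, rep("abc123", 2))
})
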