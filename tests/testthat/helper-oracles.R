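# Independent oracles and small fixtures used across the suite.

# Brute-force overlap-normalized cross-correlation (time-domain double
# loop); the reference the FFT implementation must reproduce exactly.
brute_force_nxc <- function(x, y, max_lag) {
  L <- length(y)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(k) {
    n <- max(1, 1 - k):min(L, L - k)
    num <- sum(x[n + k] * y[n])
    num / sqrt(sum(x[n + k]^2) * sum(y[n]^2))
  }, numeric(1))
  list(lags = lags, r = r)
}

# Exhaustive linear scan for the sustained threshold-crossing rule.
brute_force_crossing <- function(time, freq, threshold, sustain = 2L) {
  n <- length(freq)
  for (i in seq_len(n)) {
    if (i + sustain - 1L > n) break
    if (all(is.finite(freq[i:(i + sustain - 1L)])) &&
        all(freq[i:(i + sustain - 1L)] >= threshold))
      return(time[i])
  }
  NA_real_
}

# Coagulation-parameter rule applied directly to a (possibly true)
# frequency series, entirely via linear scans and plain means.
brute_force_parameters <- function(time, freq, rise = 0.05, end = 0.95,
                                   sustain = 2L) {
  f_int <- mean(freq[time <= min(time) + 60])
  f_end <- mean(freq[time >= max(time) - 300])
  list(f_int = f_int, f_end = f_end,
       t_int = brute_force_crossing(time, freq, (1 + rise) * f_int, sustain),
       t_end = brute_force_crossing(time, freq, end * f_end, sustain))
}

# Short acquisition used by most end-to-end tests: 10 measurements of the
# full default fast-time protocol.
short_sequence <- function(total_duration = 60, n_detection = 500) {
  pulse_sequence(total_duration = total_duration, n_detection = n_detection)
}

# Flat (non-clotting) trajectory at a chosen operating point.
flat_trajectory <- function(f = 200, a = 5e-6, beta = 20) {
  coagulation_trajectory(f_liquid = f, f_solid = f,
                         a_liquid = a, a_solid = a,
                         beta_liquid = beta, beta_solid = beta)
}

# Displacement matrix assembled directly from ideal traces (no RF, no
# tracking) for spectral-stage tests.
matrix_from_traces <- function(traces, fast_time_step, slow_time_step = 6) {
  m <- do.call(rbind, traces)
  structure(list(
    matrix = m,
    quality = matrix(1, nrow(m), ncol(m)),
    slow_times = (seq_len(nrow(m)) - 1) * slow_time_step,
    slow_time_step = slow_time_step,
    fast_time_step = fast_time_step,
    channel = 1L
  ), class = "rar_matrix")
}
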