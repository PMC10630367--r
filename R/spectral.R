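# Power spectra, spectrograms, peak tracking and damping estimation.
#
# The resonant surface-wave frequency is the peak of the power spectrum of
# the fast-time displacement trace; displayed over slow time the per-column
# normalized spectra form the spectrogram whose tracked peak f(T) carries
# the coagulation kinetics.  The spectral peak width (FWHM) and the
# time-domain envelope decay are two routes to the damping rate, a
# viscosity proxy.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector (negative
#' frequencies suppressed, positive doubled), whose modulus is the signal
#' envelope.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Power spectrum of a displacement trace
#'
#' Mean-removed, zero-padded, magnitude-squared FFT on the one-sided
#' frequency axis up to half the detection PRF. The peak frequency is
#' refined by parabolic interpolation of log-power around the maximum bin;
#' the full width at half maximum (FWHM) is read off by linear interpolation
#' at half the peak power. Scaling is such that with `pad_factor = 1` the
#' one-sided power sums to the trace energy (Parseval).
#'
#' @param trace A [track_measurement()] trace, or a numeric vector (then
#'   `fast_time_step` must be given).
#' @param pad_factor Zero-padding factor (default 8); the padded grid
#'   refines peak and width interpolation.
#' @param fast_time_step Fast-time sample interval in seconds (for plain
#'   vectors).
#' @return An object of class `rar_spectrum`: list with `frequencies` (Hz),
#'   `power`, `peak_frequency` (Hz), `peak_width_fwhm` (Hz or `NA`), and
#'   `valid`. An all-zero, non-finite, or mostly low-quality trace yields
#'   `valid = FALSE` with `NA` estimates instead of an error.
#' @export
power_spectrum <- function(trace, pad_factor = 8, fast_time_step = NULL) {
  if (inherits(trace, "rar_trace")) {
    x <- trace$values
    dt <- trace$fast_time_step
    bad_frac <- mean(trace$low_quality)
  } else {
    x <- as.numeric(trace)
    if (is.null(fast_time_step))
      stop("`fast_time_step` required for a plain vector", call. = FALSE)
    dt <- fast_time_step
    bad_frac <- 0
  }
  n <- length(x)
  if (n < 8) stop("trace too short for spectral analysis", call. = FALSE)
  pad_factor <- max(1L, as.integer(pad_factor))

  invalid <- function(frequencies = NULL, power = NULL) {
    structure(list(frequencies = frequencies, power = power,
                   peak_frequency = NA_real_, peak_width_fwhm = NA_real_,
                   valid = FALSE), class = "rar_spectrum")
  }
  if (any(!is.finite(x)) || bad_frac > 0.5) return(invalid())
  x <- x - mean(x)
  if (max(abs(x)) == 0) return(invalid())

  p <- n * pad_factor
  X <- fft(c(x, numeric(p - n)))
  n_one <- floor(p / 2) + 1L
  power <- Mod(X[seq_len(n_one)])^2 / n
  # one-sided: double everything except DC (and Nyquist when p is even)
  dbl <- 2:(n_one - if (p %% 2 == 0) 1L else 0L)
  power[dbl] <- 2 * power[dbl]
  frequencies <- (seq_len(n_one) - 1L) / (p * dt)

  ipk <- which.max(power[-1L]) + 1L   # exclude the DC bin
  pk <- power[ipk]
  off <- 0
  # refine only against neighbours that carry real signal: interpolating on
  # bins at the numerical noise floor (exact-bin tones) is meaningless
  if (ipk > 2L && ipk < n_one &&
      max(power[c(ipk - 1L, ipk + 1L)]) > pk * 1e-12) {
    lp <- log(pmax(power[(ipk - 1L):(ipk + 1L)], pk * 1e-300))
    off <- parabolic_offset(lp[1L], lp[2L], lp[3L])
  }
  peak_frequency <- (ipk - 1L + off) / (p * dt)

  half <- pk / 2
  left <- NA_real_; right <- NA_real_
  below_l <- which(power[seq_len(ipk - 1L)] < half)
  if (length(below_l)) {
    i <- max(below_l)
    left <- frequencies[i] + (half - power[i]) /
      (power[i + 1L] - power[i]) * (frequencies[i + 1L] - frequencies[i])
  }
  below_r <- which(power[(ipk + 1L):n_one] < half)
  if (length(below_r)) {
    i <- ipk + min(below_r)
    right <- frequencies[i - 1L] + (power[i - 1L] - half) /
      (power[i - 1L] - power[i]) * (frequencies[i] - frequencies[i - 1L])
  }
  fwhm <- if (is.na(left) || is.na(right)) NA_real_ else right - left

  structure(list(frequencies = frequencies, power = power,
                 peak_frequency = peak_frequency, peak_width_fwhm = fwhm,
                 valid = TRUE), class = "rar_spectrum")
}

#' @export
print.rar_spectrum <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Power spectrum: peak %.2f Hz, FWHM %s Hz\n",
                x$peak_frequency,
                if (is.na(x$peak_width_fwhm)) "NA"
                else sprintf("%.2f", x$peak_width_fwhm)))
  else cat("Power spectrum: invalid (degenerate trace)\n")
  invisible(x)
}

#' Spectrogram of a displacement matrix
#'
#' Per-measurement power spectra arranged as columns over slow time, each
#' valid column normalized to unit maximum (the conventional normalized
#' power-spectrum display). Raw power is retained alongside. Invalid rows
#' of the displacement matrix (gaps, degenerate traces) become masked
#' columns.
#'
#' @param dmatrix A [build_matrix()] displacement matrix.
#' @param pad_factor Zero-padding factor passed to [power_spectrum()].
#' @return An object of class `rar_spectrogram`: list with `slow_times`
#'   (s), `frequencies` (Hz), `normalized_power` (freq x time, each valid
#'   column max 1), `power` (raw), `peak_series` (Hz), `width_series`
#'   (Hz), `valid` (per column), `channel`.
#' @export
rar_spectrogram <- function(dmatrix, pad_factor = 8) {
  stopifnot(inherits(dmatrix, "rar_matrix"))
  M <- nrow(dmatrix$matrix)
  specs <- lapply(seq_len(M), function(m) {
    power_spectrum(dmatrix$matrix[m, ], pad_factor = pad_factor,
                   fast_time_step = dmatrix$fast_time_step)
  })
  valid <- vapply(specs, `[[`, logical(1), "valid")
  if (!any(valid)) stop("no valid measurement in displacement matrix",
                        call. = FALSE)
  frequencies <- specs[[which(valid)[1L]]]$frequencies
  nf <- length(frequencies)
  raw <- matrix(NA_real_, nf, M)
  for (m in which(valid)) raw[, m] <- specs[[m]]$power
  norm <- raw
  for (m in which(valid)) norm[, m] <- raw[, m] / max(raw[, m])
  structure(list(
    slow_times = dmatrix$slow_times,
    frequencies = frequencies,
    normalized_power = norm,
    power = raw,
    peak_series = vapply(specs, `[[`, numeric(1), "peak_frequency"),
    width_series = vapply(specs, `[[`, numeric(1), "peak_width_fwhm"),
    valid = valid,
    channel = dmatrix$channel
  ), class = "rar_spectrogram")
}

#' @export
print.rar_spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d frequencies x %d time points (%d valid), channel %d\n",
              length(x$frequencies), length(x$slow_times), sum(x$valid),
              x$channel))
  invisible(x)
}

#' Track the resonant-frequency series over slow time
#'
#' Median-filters the spectrogram peak series (default window 3, which
#' removes single-column outliers) after linearly interpolating masked
#' gaps. Monotonicity is deliberately not enforced: real series may dip.
#'
#' @param sg A [rar_spectrogram()] object.
#' @param smooth_window Odd median-filter window length (default 3);
#'   1 disables smoothing.
#' @return A data frame of class `rar_freq_series` with columns `time` (s),
#'   `frequency` (Hz) and `interpolated` (logical: column was masked).
#' @export
track_peak <- function(sg, smooth_window = 3L) {
  stopifnot(inherits(sg, "rar_spectrogram"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window %% 2 == 0)
    stop("`smooth_window` must be odd", call. = FALSE)
  ok <- sg$valid & is.finite(sg$peak_series)
  if (sum(ok) < 3L)
    stop("need at least 3 valid spectrogram columns to track the peak",
         call. = FALSE)
  t <- sg$slow_times
  f <- sg$peak_series
  if (any(!ok))
    f[!ok] <- approx(t[ok], f[ok], xout = t[!ok], rule = 2)$y
  if (smooth_window > 1L) f <- as.numeric(runmed(f, smooth_window))
  structure(data.frame(time = t, frequency = f, interpolated = !ok),
            class = c("rar_freq_series", "data.frame"))
}

#' Estimate the damping rate of an oscillatory trace
#'
#' Time-domain damping estimate: linear fit of the log envelope (modulus of
#' the analytic signal) versus fast time, with the edge regions trimmed to
#' avoid end transients of the discrete envelope. For a damped harmonic
#' oscillation `A exp(-beta tau) sin(2 pi f tau)` the negative slope is
#' `beta`. The frequency-domain counterpart is `pi * FWHM` of the spectral
#' peak (Lorentzian line width); the two agree when the line width, rather
#' than the observation window, sets the peak width.
#'
#' @param trace A tracked trace or numeric vector (with `fast_time_step`).
#' @param fast_time_step Sample interval in seconds for plain vectors.
#' @param trim Fraction of samples discarded at each end before the fit
#'   (default 0.05).
#' @return Damping rate beta in 1/s, or `NA_real_` (no-estimate sentinel)
#'   for a non-oscillatory or degenerate trace.
#' @export
estimate_damping <- function(trace, fast_time_step = NULL, trim = 0.05) {
  if (inherits(trace, "rar_trace")) {
    x <- trace$values
    dt <- trace$fast_time_step
  } else {
    x <- as.numeric(trace)
    if (is.null(fast_time_step))
      stop("`fast_time_step` required for a plain vector", call. = FALSE)
    dt <- fast_time_step
  }
  n <- length(x)
  if (n < 16 || any(!is.finite(x))) return(NA_real_)
  x <- x - mean(x)
  if (max(abs(x)) == 0) return(NA_real_)
  ps <- power_spectrum(x, pad_factor = 8, fast_time_step = dt)
  # non-oscillatory: no resolvable spectral peak above ~1.5 bins
  if (!ps$valid || !is.finite(ps$peak_frequency) ||
      ps$peak_frequency < 1.5 / (n * dt)) return(NA_real_)
  env <- Mod(analytic_signal(x))
  k <- max(1L, ceiling(trim * n))
  keep <- (k + 1L):(n - k)
  # fit the first ~3 decay constants only, as one contiguous run: below
  # exp(-3) of the peak (and again near the record edges) the discrete
  # envelope is dominated by its leakage pedestal, which flattens the
  # log-envelope tail and biases the slope for strong damping
  below <- which(env[keep] <= max(env) * exp(-3))
  if (length(below)) {
    if (below[1L] == 1L) return(NA_real_)
    keep <- keep[seq_len(below[1L] - 1L)]
  }
  if (length(keep) < 8) return(NA_real_)
  tau <- (keep - 1L) * dt
  fit <- lm(log(env[keep]) ~ tau)
  -unname(coef(fit)[2L])
}
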