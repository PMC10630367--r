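# Surface-displacement tracking from RF echoes.
#
# Each detection A-scan is compared against the averaged baseline echo by
# normalized cross-correlation inside a window around the surface echo; the
# correlation peak lag, refined to sub-sample precision by three-point
# parabolic interpolation, gives the round-trip delay change dt, and the
# displacement follows as S = c * dt / 2 under a constant, uniform sound
# speed.  Positive S = surface rising away from the transducer below it
# (longer path, later echo).

#' Echo analysis window
#'
#' Time window, relative to the start of the record gate, containing exactly
#' one surface echo at equilibrium.
#'
#' @param start_delay Window start in seconds (>= 0).
#' @param length Window length in seconds (> 0).
#' @return An object of class `rar_window`.
#' @seealso [locate_echo_window()]
#' @export
echo_window <- function(start_delay, length) {
  structure(list(
    start_delay = check_scalar(start_delay, "start_delay", non_negative = TRUE),
    length = check_scalar(length, "length", positive = TRUE)
  ), class = "rar_window")
}

window_indices <- function(window, sampling_rate, n_samples) {
  i0 <- as.integer(floor(window$start_delay * sampling_rate)) + 1L
  len <- as.integer(round(window$length * sampling_rate))
  i1 <- min(i0 + len - 1L, n_samples)
  if (i0 < 1L || i0 > n_samples || i1 <= i0)
    stop("echo window falls outside the A-scan record", call. = FALSE)
  i0:i1
}

#' Auto-locate the surface-echo window
#'
#' Finds the surface echo in an averaged baseline record as the latest
#' envelope peak exceeding a fraction of the global envelope maximum (the
#' surface echo arrives after the static plate echoes, which sit earlier in
#' the gate), and returns a window of +/- 3 pulse durations around it.
#'
#' @param template Numeric vector: averaged baseline A-scan (full record).
#' @param sampling_rate RF sampling rate in Hz.
#' @param pulse_duration Detection-pulse -6 dB duration in seconds
#'   (default 0.6e-6).
#' @param threshold Fraction of the global envelope maximum a peak must
#'   exceed to count as an echo (default 0.3).
#' @return An [echo_window()] object.
#' @export
locate_echo_window <- function(template, sampling_rate,
                               pulse_duration = 0.6e-6, threshold = 0.3) {
  stopifnot(is.numeric(template), length(template) > 8)
  env <- Mod(analytic_signal(template - mean(template)))
  floor_level <- threshold * max(env)
  # local maxima of the envelope above the floor
  n <- length(env)
  is_peak <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                      env[2:(n - 1)] >= env[3:n], FALSE) & env > floor_level
  peaks <- which(is_peak)
  if (length(peaks) == 0L)
    stop("no echo found above threshold; cannot locate surface echo",
         call. = FALSE)
  centre <- (max(peaks) - 1) / sampling_rate
  half <- 3 * pulse_duration
  start <- max(0, centre - half)
  len <- min(centre + half, (length(template) - 1) / sampling_rate) - start
  echo_window(start, len)
}

#' Averaged baseline echo template
#'
#' Pointwise mean of the baseline A-scans acquired before the push pulse.
#' Averaging mitigates pulse-to-pulse amplitude variation and reduces the
#' template noise variance by the number of scans.
#'
#' @param baseline Matrix with one baseline scan per row, or a list of
#'   equal-length numeric vectors, or a single vector.
#' @param window Optional [echo_window()]; if supplied the template is
#'   restricted to it.
#' @param sampling_rate Required when `window` is supplied.
#' @return Numeric vector: the averaged (and optionally windowed) template.
#' @export
baseline_template <- function(baseline, window = NULL, sampling_rate = NULL) {
  if (is.list(baseline) && !is.data.frame(baseline)) {
    if (length(baseline) == 0L) stop("no baseline scans", call. = FALSE)
    lens <- lengths(baseline)
    if (length(unique(lens)) != 1L)
      stop("baseline scans have mismatched lengths", call. = FALSE)
    baseline <- do.call(rbind, baseline)
  }
  if (is.vector(baseline)) baseline <- matrix(baseline, nrow = 1L)
  if (!is.matrix(baseline) || nrow(baseline) == 0L)
    stop("no baseline scans", call. = FALSE)
  template <- colMeans(baseline)
  if (!is.null(window)) {
    if (is.null(sampling_rate))
      stop("`sampling_rate` is required with a window", call. = FALSE)
    template <- template[window_indices(window, sampling_rate, length(template))]
  }
  template
}

#' Normalized cross-correlation at integer lags
#'
#' Cross-correlation of `x` against `y` at lags `-max_lag .. max_lag`,
#' normalized per lag by the energies of the overlapping segments:
#' `r[k] = sum_n x[n+k] y[n] / sqrt(sum x[n+k]^2 * sum y[n]^2)` with `n`
#' running over the overlap. Computed via FFT with sufficient zero padding
#' to be exactly linear (no circular wrap) over the requested lag range.
#'
#' @param x,y Equal-length numeric vectors.
#' @param max_lag Maximum absolute lag in samples.
#' @return List with `lags` (integer vector) and `r` (correlation values in
#'   `[-1, 1]`). Positive lag means `x` is a delayed copy of `y`.
#' @export
normalized_xcorr <- function(x, y, max_lag = 16L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  res <- xcorr_core(matrix(x, nrow = 1L), y, max_lag)
  list(lags = res$lags, r = drop(res$r))
}

# Vectorised core: X is n_scans x L (one scan per row), y length L.
# Returns lags and the n_scans x n_lags matrix of normalized correlations.
xcorr_core <- function(X, y, max_lag) {
  L <- length(y)
  max_lag <- min(as.integer(max_lag), L - 1L)
  lags <- (-max_lag):max_lag
  P <- nextn(L + max_lag + 1L, 2)

  Xp <- matrix(0, nrow = P, ncol = nrow(X))
  Xp[seq_len(L), ] <- t(X)
  yp <- c(y, numeric(P - L))
  Z <- mvfft(mvfft(Xp) * Conj(fft(yp)), inverse = TRUE) / P
  # circular correlation: lag k >= 0 at row k+1, lag k < 0 at row P+k+1
  rows <- ifelse(lags >= 0, lags + 1L, P + lags + 1L)
  num <- Re(t(Z[rows, , drop = FALSE]))          # n_scans x n_lags

  # per-lag overlap energies via cumulative sums
  cy <- c(0, cumsum(y^2))
  cx <- cbind(0, t(apply(X^2, 1L, cumsum)))      # n_scans x (L+1)
  n_lo <- pmax(1L, 1L - lags)
  n_hi <- pmin(L, L - lags)
  ey <- cy[n_hi + 1L] - cy[n_lo]                 # template overlap energy
  ex <- cx[, n_hi + lags + 1L, drop = FALSE] - cx[, n_lo + lags, drop = FALSE]
  den <- sqrt(sweep(ex, 2L, ey, `*`))
  r <- num / den
  r[!is.finite(r)] <- 0
  list(lags = lags, r = r)
}

# Three-point parabolic interpolation around an interior peak; returns the
# sub-sample offset in (-0.5, 0.5] (0 when the curvature is degenerate).
parabolic_offset <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  off <- ifelse(abs(denom) < .Machine$double.eps * 4, 0,
                0.5 * (y_m1 - y_p1) / denom)
  pmin(pmax(off, -0.5), 0.5)
}

# Peak pick + parabolic refinement for a correlation matrix (rows = scans).
refine_delays <- function(lags, R, sampling_rate) {
  n_lag <- length(lags)
  idx <- max.col(R, ties.method = "first")
  peak <- R[cbind(seq_len(nrow(R)), idx)]
  interior <- idx > 1L & idx < n_lag
  off <- numeric(nrow(R))
  if (any(interior)) {
    i <- which(interior)
    off[i] <- parabolic_offset(R[cbind(i, idx[i] - 1L)],
                               R[cbind(i, idx[i])],
                               R[cbind(i, idx[i] + 1L)])
  }
  list(delay = (lags[idx] + off) / sampling_rate, peak = peak,
       at_edge = !interior)
}

#' Estimate the echo delay of one scan against a template
#'
#' Lag maximizing the normalized cross-correlation, refined by three-point
#' parabolic interpolation around the integer-lag peak. A correlation peak
#' below `quality_floor` flags the result as low quality rather than
#' raising an error (long acquisitions must survive transient dropouts).
#'
#' @param scan A [synthesize_ascan()] object or numeric vector.
#' @param template Numeric vector (full record) to correlate against,
#'   typically from [baseline_template()].
#' @param window Optional [echo_window()] applied to both signals.
#' @param sampling_rate RF sampling rate in Hz; taken from the scan object
#'   when available.
#' @param max_lag Integer-lag search half-range in samples (default 16).
#' @param quality_floor Minimum acceptable correlation peak (default 0.5).
#' @return List with `delay` (seconds; positive = echo arrives later than in
#'   the template), `quality` (peak correlation) and `low_quality` flag.
#' @export
estimate_delay <- function(scan, template, window = NULL,
                           sampling_rate = NULL, max_lag = 16L,
                           quality_floor = 0.5) {
  if (inherits(scan, "rar_ascan")) {
    sampling_rate <- scan$sampling_rate
    scan <- scan$samples
  }
  if (is.null(sampling_rate))
    stop("`sampling_rate` required when `scan` is a plain vector", call. = FALSE)
  stopifnot(length(scan) == length(template))
  if (!is.null(window)) {
    idx <- window_indices(window, sampling_rate, length(scan))
    scan <- scan[idx]
    template <- template[idx]
  }
  res <- xcorr_core(matrix(scan, nrow = 1L), template, max_lag)
  out <- refine_delays(res$lags, res$r, sampling_rate)
  list(delay = out$delay[1L], quality = out$peak[1L],
       low_quality = out$peak[1L] < quality_floor || out$at_edge[1L])
}

#' Convert an echo delay change to surface displacement
#'
#' `S = c * dt / 2`: the pulse travels to the surface and back, so half the
#' round-trip delay change times the sound speed is the displacement.
#'
#' @param delay Delay change(s) in seconds (vectorised; `NA` propagates).
#' @param geometry A [well_geometry()] supplying the sound speed.
#' @return Displacement in metres; positive = surface moved away from the
#'   transducer.
#' @examples
#' delay_to_displacement(13.51e-9, well_geometry())  # ~10 um
#' @export
delay_to_displacement <- function(delay, geometry) {
  stopifnot(inherits(geometry, "rar_geometry"))
  geometry$sound_speed * delay / 2
}

#' Track one measurement into a displacement trace
#'
#' Averages the baseline scans into a template, estimates the delay of each
#' of the `n_detection` post-push scans by windowed normalized
#' cross-correlation with parabolic sub-sample refinement, and converts
#' delays to displacements.
#'
#' @param measurement One element of a [simulate_channel()] `measurements`
#'   list (fields `baseline`, `detection`, `slow_time`), or a list with
#'   those fields built from real data.
#' @param window [echo_window()] around the surface echo; `NULL` to
#'   auto-locate with [locate_echo_window()].
#' @param geometry A [well_geometry()].
#' @param seq A [pulse_sequence()] (fast-time step and sampling rate).
#' @param max_lag,quality_floor Passed to the delay estimator.
#' @return An object of class `rar_trace`: list with `values` (m),
#'   `fast_time_step` (s), `slow_time` (s), `quality` (per-point peak
#'   correlation) and `low_quality` (logical).
#' @export
track_measurement <- function(measurement, window = NULL, geometry,
                              seq, max_lag = 16L, quality_floor = 0.5) {
  stopifnot(inherits(geometry, "rar_geometry"), inherits(seq, "rar_sequence"),
            is.matrix(measurement$detection))
  fs <- seq$sampling_rate
  full_template <- baseline_template(measurement$baseline)
  if (is.null(window))
    window <- locate_echo_window(full_template, fs)
  idx <- window_indices(window, fs, length(full_template))
  template <- full_template[idx]
  D <- measurement$detection[, idx, drop = FALSE]
  res <- xcorr_core(D, template, max_lag)
  ref <- refine_delays(res$lags, res$r, fs)
  values <- delay_to_displacement(ref$delay, geometry)
  structure(list(values = values,
                 fast_time_step = 1 / seq$detection_prf,
                 slow_time = measurement$slow_time,
                 quality = ref$peak,
                 low_quality = ref$peak < quality_floor | ref$at_edge),
            class = "rar_trace")
}

#' Build the 2-D displacement matrix of a channel
#'
#' Applies [track_measurement()] to every measurement of a channel dataset
#' and stacks the traces into the displacement matrix `S(T_m, tau_n)` (rows:
#' slow time, columns: fast time). Missing measurements (`NULL` entries)
#' become all-`NA` rows so the matrix stays rectangular.
#'
#' @param channel A [simulate_channel()] dataset (or a compatible list from
#'   [read_rar()]).
#' @param window Optional [echo_window()]; auto-located from the first
#'   available measurement when `NULL`.
#' @param max_lag,quality_floor Passed to the delay estimator.
#' @return An object of class `rar_matrix`: list with `matrix` (M x N, m),
#'   `quality` (M x N), `slow_times` (s), `slow_time_step`,
#'   `fast_time_step`, `channel`.
#' @export
build_matrix <- function(channel, window = NULL, max_lag = 16L,
                         quality_floor = 0.5) {
  stopifnot(inherits(channel, "rar_channel"))
  seq_ <- channel$sequence
  geometry <- channel$geometry
  present <- !vapply(channel$measurements, is.null, logical(1))
  if (!any(present)) stop("channel has no measurements", call. = FALSE)
  if (is.null(window)) {
    first <- channel$measurements[[which(present)[1L]]]
    window <- locate_echo_window(baseline_template(first$baseline),
                                 seq_$sampling_rate)
  }
  M <- length(channel$measurements)
  N <- seq_$n_detection
  mat <- matrix(NA_real_, M, N)
  qual <- matrix(NA_real_, M, N)
  slow_times <- numeric(M)
  for (m in seq_len(M)) {
    meas <- channel$measurements[[m]]
    if (is.null(meas)) {
      slow_times[m] <- (m - 1) * seq_$measurement_interval
      next
    }
    tr <- track_measurement(meas, window, geometry, seq_, max_lag,
                            quality_floor)
    mat[m, ] <- tr$values
    qual[m, ] <- tr$quality
    slow_times[m] <- meas$slow_time
  }
  structure(list(matrix = mat, quality = qual, slow_times = slow_times,
                 slow_time_step = seq_$measurement_interval,
                 fast_time_step = 1 / seq_$detection_prf,
                 channel = channel$channel),
            class = "rar_matrix")
}

#' @export
print.rar_matrix <- function(x, ...) {
  cat(sprintf(
    "Displacement matrix S(T_m, tau_n): %d x %d (dT = %g s, dtau = %g us), channel %d\n",
    nrow(x$matrix), ncol(x$matrix), x$slow_time_step,
    x$fast_time_step * 1e6, x$channel))
  invisible(x)
}
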