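# Synthetic multichannel RF pulse-echo generator.
#
# Emulates what the digitizer of a pulse-echo RAR system records: each A-scan
# is a gated RF trace containing two static echoes from the well-plate
# interfaces and one echo from the sample's top (air-sample) surface.  The
# surface echo is a Gabor pulse (Gaussian-enveloped carrier) whose round-trip
# delay moves by 2*S/c when the surface is displaced by S; surface motion
# after each push is a damped harmonic oscillation whose frequency, amplitude
# and damping follow a planted liquid-to-solid coagulation trajectory.  The
# generator supplies exact ground truth for every downstream stage.

#' Planted coagulation trajectory
#'
#' Ground-truth schedule of the resonant surface wave through a
#' liquid-to-solid transition: the resonant frequency rises from `f_liquid`
#' to `f_solid` along a logistic in elapsed time, while the oscillation
#' amplitude collapses from `A_liquid` to `A_solid` and the damping rate
#' rises from `beta_liquid` to `beta_solid` along the same logistic (the
#' three changes are concurrent during clotting). Before `lag` seconds the
#' sample is held in its liquid state. Setting `f_solid = f_liquid` (with
#' matching amplitude/damping endpoints) produces a non-clotting control.
#'
#' Defaults emulate a normal plasma sample triggered into coagulation:
#' a 90 s lag phase, a rapid transition centred at 120 s with a 10 s
#' logistic width, resonant frequency rising from 100 to 300 Hz, 5 um
#' initial surface oscillation collapsing to 0.5 um, and damping rising
#' from 20 to 150 1/s.
#'
#' @param f_liquid,f_solid Resonant frequency (Hz) in the liquid and final
#'   solid state; `f_solid >= f_liquid > 0`.
#' @param t_mid Transition midpoint in seconds.
#' @param width Logistic transition width in seconds; > 0.
#' @param lag Lag-phase duration in seconds; the trajectory is frozen at its
#'   liquid values for `T < lag`.
#' @param a_liquid,a_solid Surface oscillation amplitude (m);
#'   `a_liquid >= a_solid >= 0`.
#' @param beta_liquid,beta_solid Damping rate (1/s);
#'   `beta_solid >= beta_liquid > 0`.
#' @return An object of class `rar_trajectory`.
#' @export
coagulation_trajectory <- function(f_liquid = 100, f_solid = 300,
                                   t_mid = 120, width = 10, lag = 90,
                                   a_liquid = 5e-6, a_solid = 0.5e-6,
                                   beta_liquid = 20, beta_solid = 150) {
  f_liquid <- check_scalar(f_liquid, "f_liquid", positive = TRUE)
  f_solid <- check_scalar(f_solid, "f_solid", positive = TRUE)
  if (f_solid < f_liquid)
    stop("`f_solid` must be >= `f_liquid`", call. = FALSE)
  a_liquid <- check_scalar(a_liquid, "a_liquid", non_negative = TRUE)
  a_solid <- check_scalar(a_solid, "a_solid", non_negative = TRUE)
  if (a_solid > a_liquid)
    stop("`a_solid` must be <= `a_liquid`", call. = FALSE)
  beta_liquid <- check_scalar(beta_liquid, "beta_liquid", positive = TRUE)
  beta_solid <- check_scalar(beta_solid, "beta_solid", positive = TRUE)
  if (beta_solid < beta_liquid)
    stop("`beta_solid` must be >= `beta_liquid`", call. = FALSE)
  structure(list(
    f_liquid = f_liquid, f_solid = f_solid,
    t_mid = check_scalar(t_mid, "t_mid", non_negative = TRUE),
    width = check_scalar(width, "width", positive = TRUE),
    lag = check_scalar(lag, "lag", non_negative = TRUE),
    a_liquid = a_liquid, a_solid = a_solid,
    beta_liquid = beta_liquid, beta_solid = beta_solid
  ), class = "rar_trajectory")
}

#' @export
print.rar_trajectory <- function(x, ...) {
  cat(sprintf(
    "Coagulation trajectory: f %g -> %g Hz, lag %g s, midpoint %g s (width %g s)\n",
    x$f_liquid, x$f_solid, x$lag, x$t_mid, x$width))
  cat(sprintf("  amplitude %g -> %g um, damping %g -> %g 1/s\n",
              x$a_liquid * 1e6, x$a_solid * 1e6, x$beta_liquid, x$beta_solid))
  invisible(x)
}

# Shared logistic schedule in [0, 1]: 0 in the lag phase, then the plain
# logistic of elapsed time.  Monotone non-decreasing provided
# logistic((lag - t_mid)/width) is small, which all sensible
# parameterisations satisfy; the clamp guarantees the frozen lag phase.
trajectory_progress <- function(traj, t) {
  ifelse(t < traj$lag, 0, logistic((t - traj$t_mid) / traj$width))
}

#' Trajectory frequency schedule
#'
#' Planted resonant frequency at elapsed time `t`:
#' `f_liquid + (f_solid - f_liquid) * logistic((t - t_mid)/width)`, held at
#' `f_liquid` during the lag phase. Monotone non-decreasing.
#'
#' @param traj A [coagulation_trajectory()].
#' @param t Elapsed time(s) in seconds; >= 0. Vectorised.
#' @return Frequency in Hz.
#' @export
trajectory_frequency <- function(traj, t) {
  stopifnot(inherits(traj, "rar_trajectory"), all(t >= 0))
  traj$f_liquid + (traj$f_solid - traj$f_liquid) * trajectory_progress(traj, t)
}

#' Trajectory amplitude schedule
#'
#' @inheritParams trajectory_frequency
#' @return Oscillation amplitude in metres (non-increasing in `t`).
#' @export
trajectory_amplitude <- function(traj, t) {
  stopifnot(inherits(traj, "rar_trajectory"), all(t >= 0))
  traj$a_liquid + (traj$a_solid - traj$a_liquid) * trajectory_progress(traj, t)
}

#' Trajectory damping schedule
#'
#' @inheritParams trajectory_frequency
#' @return Damping rate in 1/s (non-decreasing in `t`).
#' @export
trajectory_damping <- function(traj, t) {
  stopifnot(inherits(traj, "rar_trajectory"), all(t >= 0))
  traj$beta_liquid + (traj$beta_solid - traj$beta_liquid) *
    trajectory_progress(traj, t)
}

#' True surface motion after one push
#'
#' Damped harmonic oscillation of the surface centre point sampled on the
#' detection fast-time grid: `S(tau_n) = A(T) exp(-beta(T) tau_n)
#' sin(2 pi f(T) tau_n)` with `tau_n = n / detection_prf`, `n = 0..N-1`.
#'
#' @param traj A [coagulation_trajectory()].
#' @param t Elapsed (slow) time of the measurement, seconds.
#' @param seq A [pulse_sequence()].
#' @return Numeric vector of `n_detection` displacements in metres
#'   (first sample, at `tau = 0`, is zero).
#' @export
surface_motion <- function(traj, t, seq) {
  stopifnot(inherits(traj, "rar_trajectory"), inherits(seq, "rar_sequence"))
  tau <- (seq_len(seq$n_detection) - 1) / seq$detection_prf
  trajectory_amplitude(traj, t) * exp(-trajectory_damping(traj, t) * tau) *
    sin(2 * pi * trajectory_frequency(traj, t) * tau)
}

#' Echo model of the gated RF record
#'
#' Geometry of what the digitizer gate contains: two static plate echoes
#' (well-plate bottom and plate-sample interface) followed by the moving
#' echo from the sample's top surface. Echoes are Gabor pulses at the
#' carrier frequency with a Gaussian envelope whose -6 dB full duration is
#' `pulse_duration` (default 0.6 us, a typical short detection pulse at
#' 5 MHz). Times are relative to the start of the record gate.
#'
#' @param surface_delay Nominal (equilibrium) round-trip delay of the
#'   surface echo within the gate, seconds.
#' @param plate_delays Delays of the static plate echoes, seconds.
#' @param plate_amplitudes Relative amplitudes of the plate echoes.
#' @param amplitude Peak amplitude of the surface echo (arbitrary units; the
#'   simulated digitizer is linear so the scale is free).
#' @param pulse_duration -6 dB full duration of the echo envelope, seconds.
#' @param gate_length Length of the recorded gate, seconds.
#' @return An object of class `rar_echo_model`.
#' @export
echo_model <- function(surface_delay = 3.0e-6,
                       plate_delays = c(0.5e-6, 1.0e-6),
                       plate_amplitudes = c(0.6, 0.4),
                       amplitude = 1.0,
                       pulse_duration = 0.6e-6,
                       gate_length = 5.0e-6) {
  stopifnot(length(plate_delays) == length(plate_amplitudes))
  structure(list(
    surface_delay = check_scalar(surface_delay, "surface_delay", positive = TRUE),
    plate_delays = as.numeric(plate_delays),
    plate_amplitudes = as.numeric(plate_amplitudes),
    amplitude = check_scalar(amplitude, "amplitude", positive = TRUE),
    pulse_duration = check_scalar(pulse_duration, "pulse_duration",
                                  positive = TRUE),
    gate_length = check_scalar(gate_length, "gate_length", positive = TRUE)
  ), class = "rar_echo_model")
}

# Gaussian envelope sigma from the -6 dB full duration (amplitude = 1/2 at
# +/- duration/2):  w = (d/2) / sqrt(2 ln 2).
gabor_sigma <- function(pulse_duration) (pulse_duration / 2) / sqrt(2 * log(2))

# Matrix of RF records for a vector of surface displacements; one row per
# scan.  Echoes are evaluated in closed form at the exact continuous-time
# delay, so sub-sample displacement placement is exact (no oversampling
# grid).  noise_sd = 0 disables noise.
synth_records <- function(displacements, seq, geometry, echo, noise_sd = 0) {
  fs <- seq$sampling_rate
  if (fs < 4 * seq$carrier_frequency)
    stop(sprintf(
      "sampling_rate (%.3g Hz) must be at least 4x carrier_frequency (%.3g Hz) to avoid aliasing",
      fs, seq$carrier_frequency), call. = FALSE)
  n_samp <- as.integer(round(echo$gate_length * fs))
  t_grid <- (seq_len(n_samp) - 1) / fs
  w <- gabor_sigma(echo$pulse_duration)
  fc <- seq$carrier_frequency

  static <- numeric(n_samp)
  for (j in seq_along(echo$plate_delays)) {
    dt <- t_grid - echo$plate_delays[j]
    static <- static + echo$plate_amplitudes[j] *
      exp(-dt^2 / (2 * w^2)) * cos(2 * pi * fc * dt)
  }

  delays <- echo$surface_delay + 2 * displacements / geometry$sound_speed
  # outer(): n_scans x n_samp matrix of (t - delay_i)
  dt <- outer(-delays, t_grid, `+`)
  rf <- echo$amplitude * exp(-dt^2 / (2 * w^2)) * cos(2 * pi * fc * dt)
  rf <- sweep(rf, 2, static, `+`)
  if (noise_sd > 0)
    rf <- rf + matrix(rnorm(length(rf), sd = noise_sd), nrow = nrow(rf))
  rf
}

noise_sd_from_snr <- function(echo, noise_snr_db) {
  if (is.null(noise_snr_db) || !is.finite(noise_snr_db)) return(0)
  echo$amplitude / 10^(noise_snr_db / 20)
}

#' Synthesize one A-scan
#'
#' Single gated RF record for a given instantaneous surface displacement.
#' The surface-echo round-trip delay is `surface_delay + 2 * displacement /
#' sound_speed`; positive displacement means the surface has risen away from
#' the transducer below it, so the echo arrives later.
#'
#' @param displacement Surface displacement in metres.
#' @param geometry A [well_geometry()] (supplies the sound speed).
#' @param seq A [pulse_sequence()] (supplies carrier and sampling rate).
#' @param echo An [echo_model()].
#' @param noise_snr_db Additive white Gaussian noise level as SNR in dB
#'   relative to the surface-echo peak amplitude; `Inf` (default) disables
#'   noise.
#' @param slow_time,fast_time,channel Metadata stamped on the scan; baseline
#'   scans carry negative `fast_time`.
#' @return An object of class `rar_ascan`: list with `samples`,
#'   `sampling_rate`, `slow_time`, `fast_time`, `channel`.
#' @export
synthesize_ascan <- function(displacement, geometry, seq, echo = echo_model(),
                             noise_snr_db = Inf, slow_time = 0,
                             fast_time = 0, channel = 1L) {
  stopifnot(inherits(geometry, "rar_geometry"), inherits(seq, "rar_sequence"),
            inherits(echo, "rar_echo_model"))
  displacement <- check_scalar(displacement, "displacement")
  max_shift <- abs(2 * displacement / geometry$sound_speed)
  if (echo$surface_delay + max_shift + 3 * gabor_sigma(echo$pulse_duration) >
      echo$gate_length)
    warning("surface echo extends beyond the record gate; increase gate_length")
  samples <- drop(synth_records(displacement, seq, geometry, echo,
                                noise_sd = noise_sd_from_snr(echo, noise_snr_db)))
  structure(list(samples = samples, sampling_rate = seq$sampling_rate,
                 slow_time = slow_time, fast_time = fast_time,
                 channel = as.integer(channel)),
            class = "rar_ascan")
}

#' Simulate one acquisition channel
#'
#' Full slow-time acquisition for one well: at each slow-time point
#' `T_m = m * measurement_interval` (`m = 0 .. M-1`,
#' `M = total_duration / measurement_interval`) the generator emits
#' `n_baseline` baseline scans of the equilibrium surface followed by
#' `n_detection` scans sampling the damped surface oscillation given by the
#' planted trajectory. Deterministic for a fixed seed; the session RNG state
#' is left untouched.
#'
#' @param traj A [coagulation_trajectory()] (stored as ground truth).
#' @param seq A [pulse_sequence()].
#' @param geometry A [well_geometry()].
#' @param echo An [echo_model()].
#' @param noise_snr_db Noise SNR in dB re the surface-echo peak (default 30);
#'   `Inf` disables noise.
#' @param seed Integer RNG seed.
#' @param channel Channel index stamped on the dataset.
#' @return An object of class `rar_channel`: list with `sequence`,
#'   `geometry`, `echo`, `noise_snr_db`, `seed`, `channel`, `truth`, and
#'   `measurements` — a list of `M` elements, each holding `slow_time`, a
#'   `baseline` matrix (`n_baseline` x samples) and a `detection` matrix
#'   (`n_detection` x samples).
#' @export
simulate_channel <- function(traj, seq = pulse_sequence(),
                             geometry = well_geometry(), echo = echo_model(),
                             noise_snr_db = 30, seed = 1L, channel = 1L) {
  stopifnot(inherits(traj, "rar_trajectory"), inherits(seq, "rar_sequence"))
  m_count <- n_measurements(seq)
  noise_sd <- noise_sd_from_snr(echo, noise_snr_db)
  measurements <- with_seed(seed, {
    lapply(seq_len(m_count), function(m) {
      t_slow <- (m - 1) * seq$measurement_interval
      s_det <- surface_motion(traj, t_slow, seq)
      baseline <- synth_records(rep(0, seq$n_baseline), seq, geometry, echo,
                                noise_sd = noise_sd)
      detection <- synth_records(s_det, seq, geometry, echo,
                                 noise_sd = noise_sd)
      list(slow_time = t_slow, baseline = baseline, detection = detection)
    })
  })
  structure(list(sequence = seq, geometry = geometry, echo = echo,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed),
                 channel = as.integer(channel), truth = traj,
                 measurements = measurements),
            class = "rar_channel")
}

#' @export
print.rar_channel <- function(x, ...) {
  cat(sprintf("RAR channel %d: %d measurements (dT = %g s), seed %d, SNR %g dB\n",
              x$channel, length(x$measurements),
              x$sequence$measurement_interval, x$seed, x$noise_snr_db))
  invisible(x)
}

#' Simulate a multichannel plate
#'
#' Synchronized acquisition of several wells: all channels share the same
#' pulse sequence and slow-time grid, with one planted trajectory and an
#' independent noise stream per channel. The default four channels mirror a
#' four-transducer array under adjacent wells of a 96-well plate.
#'
#' @param trajectories List of [coagulation_trajectory()] objects, one per
#'   channel (default four identical normal-plasma trajectories).
#' @inheritParams simulate_channel
#' @return An object of class `rar_plate`: list with shared `sequence`,
#'   `geometry`, `echo`, `noise_snr_db`, `seed`, and `channels` — a list of
#'   `rar_channel` datasets.
#' @export
simulate_plate <- function(trajectories = rep(list(coagulation_trajectory()), 4),
                           seq = pulse_sequence(), geometry = well_geometry(),
                           echo = echo_model(), noise_snr_db = 30, seed = 1L) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1,
            length(trajectories) <= 96)
  channels <- lapply(seq_along(trajectories), function(i) {
    simulate_channel(trajectories[[i]], seq, geometry, echo, noise_snr_db,
                     seed = as.integer(seed) + 1000L * i, channel = i)
  })
  structure(list(sequence = seq, geometry = geometry, echo = echo,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed),
                 channels = channels),
            class = "rar_plate")
}

#' @export
print.rar_plate <- function(x, ...) {
  cat(sprintf("RAR plate: %d channels x %d measurements, seed %d\n",
              length(x$channels), length(x$channels[[1]]$measurements), x$seed))
  invisible(x)
}
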