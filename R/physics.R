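# Dispersion relations for resonant surface waves, their inversions to
# material properties, and pulse-sequence timing arithmetic.
#
# In a cylindrical well the lowest axisymmetric resonant surface-wave mode
# fixes the wavenumber k = alpha / R, where alpha is the mode constant
# (default 2.4048, the first zero of the Bessel function J0, i.e. a pinned
# contact line) and R the well radius.  A liquid surface carries capillary
# waves, f = (1/2pi) sqrt(sigma k^3 / rho); a soft solid carries Rayleigh
# waves, f = (1/2pi) sqrt(G k^2 / rho).  Measuring f therefore yields the
# surface tension sigma of a liquid or the shear modulus G of a gel.

#' Well geometry for resonant surface-wave analysis
#'
#' Describes the cylindrical sample well and the acoustic medium. The
#' resonant wavenumber is `mode_constant / radius`; the default mode constant
#' 2.4048 is the first zero of the zeroth-order Bessel function, i.e. the
#' fundamental axisymmetric mode with a pinned contact line. The boundary
#' condition is not universal, so the constant is exposed rather than fixed.
#'
#' @param radius Well radius in metres (default 3.25e-3, a standard
#'   96-well microplate well).
#' @param mode_constant Dimensionless resonant-mode eigenvalue (default
#'   2.4048).
#' @param density Sample mass density in kg/m^3 (default 1000).
#' @param sound_speed Speed of sound used for echo-delay conversion, m/s
#'   (default 1480, water at roughly body temperature).
#' @return An object of class `rar_geometry`.
#' @seealso [wavenumber()], [invert_shear_modulus()]
#' @examples
#' g <- well_geometry()
#' wavenumber(g)  # ~739.94 1/m
#' @export
well_geometry <- function(radius = 3.25e-3, mode_constant = 2.4048,
                          density = 1000, sound_speed = 1480) {
  out <- list(
    radius = check_scalar(radius, "radius", positive = TRUE),
    mode_constant = check_scalar(mode_constant, "mode_constant", positive = TRUE),
    density = check_scalar(density, "density", positive = TRUE),
    sound_speed = check_scalar(sound_speed, "sound_speed", positive = TRUE)
  )
  structure(out, class = "rar_geometry")
}

#' @export
print.rar_geometry <- function(x, ...) {
  cat("Well geometry: R =", format(x$radius), "m, alpha =", x$mode_constant,
      "\n  density =", x$density, "kg/m^3, sound speed =", x$sound_speed,
      "m/s, k =", format(wavenumber(x)), "1/m\n")
  invisible(x)
}

#' Material surface state
#'
#' Holds the material properties entering the surface-wave dispersion
#' relations: surface tension (liquid regime) and/or shear modulus (solid
#' regime). At least one of the two must be given.
#'
#' @param surface_tension Surface tension sigma in N/m, or `NULL`.
#' @param shear_modulus Shear modulus G in Pa, or `NULL`.
#' @param density Mass density rho in kg/m^3.
#' @return An object of class `rar_material`.
#' @examples
#' plasma <- material_state(surface_tension = 0.072, density = 1000)
#' clot <- material_state(shear_modulus = 500, density = 1000)
#' @export
material_state <- function(surface_tension = NULL, shear_modulus = NULL,
                           density = 1000) {
  if (is.null(surface_tension) && is.null(shear_modulus))
    stop("at least one of `surface_tension`, `shear_modulus` must be given",
         call. = FALSE)
  if (!is.null(surface_tension))
    surface_tension <- check_scalar(surface_tension, "surface_tension",
                                    non_negative = TRUE)
  if (!is.null(shear_modulus))
    shear_modulus <- check_scalar(shear_modulus, "shear_modulus",
                                  non_negative = TRUE)
  structure(list(
    surface_tension = surface_tension,
    shear_modulus = shear_modulus,
    density = check_scalar(density, "density", positive = TRUE)
  ), class = "rar_material")
}

#' Resonant surface-wave wavenumber of a well
#'
#' @param geometry A [well_geometry()] object.
#' @return Wavenumber k = mode_constant / radius, in 1/m.
#' @export
wavenumber <- function(geometry) {
  stopifnot(inherits(geometry, "rar_geometry"))
  geometry$mode_constant / geometry$radius
}

#' Capillary-wave frequency
#'
#' Frequency of a capillary (surface-tension-restored) wave,
#' `f = (1/2pi) * sqrt(sigma * k^3 / rho)`. This is the liquid-regime
#' dispersion relation; it increases with surface tension and wavenumber.
#'
#' @param material A [material_state()] with `surface_tension` present.
#' @param k Wavenumber in 1/m; must be positive.
#' @return Frequency in Hz.
#' @examples
#' m <- material_state(surface_tension = 0.072, density = 1000)
#' capillary_frequency(m, k = 739.94)  # ~27.2 Hz
#' @export
capillary_frequency <- function(material, k) {
  stopifnot(inherits(material, "rar_material"))
  if (is.null(material$surface_tension))
    stop("material has no `surface_tension`; capillary dispersion undefined",
         call. = FALSE)
  k <- check_scalar(k, "k", positive = TRUE)
  sqrt(material$surface_tension * k^3 / material$density) / (2 * pi)
}

#' Rayleigh-wave frequency
#'
#' Frequency of a Rayleigh (elasticity-restored) surface wave on a soft
#' solid, `f = (1/2pi) * sqrt(G * k^2 / rho)`; linear in k at fixed modulus.
#'
#' @param material A [material_state()] with `shear_modulus` present.
#' @param k Wavenumber in 1/m; must be positive.
#' @return Frequency in Hz.
#' @examples
#' m <- material_state(shear_modulus = 500, density = 1000)
#' rayleigh_frequency(m, k = 739.94)  # ~83.3 Hz
#' @export
rayleigh_frequency <- function(material, k) {
  stopifnot(inherits(material, "rar_material"))
  if (is.null(material$shear_modulus))
    stop("material has no `shear_modulus`; Rayleigh dispersion undefined",
         call. = FALSE)
  k <- check_scalar(k, "k", positive = TRUE)
  sqrt(material$shear_modulus * k^2 / material$density) / (2 * pi)
}

#' Invert a resonant frequency to shear modulus
#'
#' Exact inverse of [rayleigh_frequency()] for the wavenumber fixed by the
#' well geometry: `G = (2 pi f)^2 rho / k^2`. `NA` frequencies (no-estimate
#' sentinels from upstream stages) propagate as `NA`.
#'
#' @param frequency Resonant frequency in Hz (vectorised); must be >= 0.
#' @param geometry A [well_geometry()] object.
#' @return Shear modulus in Pa.
#' @export
invert_shear_modulus <- function(frequency, geometry) {
  stopifnot(inherits(geometry, "rar_geometry"), is.numeric(frequency))
  if (any(frequency < 0, na.rm = TRUE))
    stop("`frequency` must be non-negative", call. = FALSE)
  k <- wavenumber(geometry)
  (2 * pi * frequency)^2 * geometry$density / k^2
}

#' Invert a resonant frequency to surface tension
#'
#' Exact inverse of [capillary_frequency()]: `sigma = (2 pi f)^2 rho / k^3`.
#'
#' @inheritParams invert_shear_modulus
#' @return Surface tension in N/m.
#' @export
invert_surface_tension <- function(frequency, geometry) {
  stopifnot(inherits(geometry, "rar_geometry"), is.numeric(frequency))
  if (any(frequency < 0, na.rm = TRUE))
    stop("`frequency` must be non-negative", call. = FALSE)
  k <- wavenumber(geometry)
  (2 * pi * frequency)^2 * geometry$density / k^3
}

#' Transducer f-number
#'
#' Ratio of focal distance to aperture diameter.
#'
#' @param focal_distance Focal distance in metres; > 0.
#' @param aperture_diameter Active aperture diameter in metres; > 0.
#' @return Dimensionless f-number.
#' @examples
#' f_number(12.3e-3, 5.0e-3)  # 2.46
#' @export
f_number <- function(focal_distance, aperture_diameter) {
  focal_distance <- check_scalar(focal_distance, "focal_distance", positive = TRUE)
  aperture_diameter <- check_scalar(aperture_diameter, "aperture_diameter",
                                    positive = TRUE)
  focal_distance / aperture_diameter
}

#' Pulse sequence of one RAR measurement
#'
#' One measurement consists of `n_baseline` pulse-echo acquisitions of the
#' surface at equilibrium, a single long "push" tone burst whose radiation
#' force perturbs the surface, and `n_detection` pulse-echo acquisitions at
#' the detection pulse-repetition frequency (PRF) that sample the resulting
#' resonant oscillation. Measurements repeat every `measurement_interval`
#' seconds over `total_duration`.
#'
#' @param n_baseline Number of baseline detection pulses (default 20).
#' @param push_cycles Cycles in the push tone burst (default 100).
#' @param carrier_frequency Transducer carrier frequency in Hz (default 5 MHz).
#' @param detection_prf Detection pulse-repetition frequency in Hz
#'   (default 10 kHz); the fast-time step is its inverse.
#' @param n_detection Number of post-push detection pulses (default 500).
#' @param sampling_rate RF digitizer sampling rate in Hz (default 62.5 MHz).
#' @param measurement_interval Slow-time interval between measurements in
#'   seconds (default 6).
#' @param total_duration Total observation time in seconds (default 3600).
#' @return An object of class `rar_sequence`.
#' @seealso [sequence_timing()]
#' @export
pulse_sequence <- function(n_baseline = 20, push_cycles = 100,
                           carrier_frequency = 5.0e6, detection_prf = 1.0e4,
                           n_detection = 500, sampling_rate = 62.5e6,
                           measurement_interval = 6.0, total_duration = 3600) {
  out <- list(
    n_baseline = check_count(n_baseline, "n_baseline", minimum = 0L),
    push_cycles = check_count(push_cycles, "push_cycles", minimum = 1L),
    carrier_frequency = check_scalar(carrier_frequency, "carrier_frequency",
                                     positive = TRUE),
    detection_prf = check_scalar(detection_prf, "detection_prf", positive = TRUE),
    n_detection = check_count(n_detection, "n_detection", minimum = 0L),
    sampling_rate = check_scalar(sampling_rate, "sampling_rate", positive = TRUE),
    measurement_interval = check_scalar(measurement_interval,
                                        "measurement_interval", positive = TRUE),
    total_duration = check_scalar(total_duration, "total_duration",
                                  positive = TRUE)
  )
  if (out$detection_prf > out$sampling_rate)
    stop("`detection_prf` cannot exceed `sampling_rate`", call. = FALSE)
  structure(out, class = "rar_sequence")
}

#' @export
print.rar_sequence <- function(x, ...) {
  tm <- sequence_timing(x)
  cat("RAR pulse sequence:\n",
      sprintf("  %d baseline + push (%d cycles @ %.2f MHz) + %d detection @ %.1f kHz PRF\n",
              x$n_baseline, x$push_cycles, x$carrier_frequency / 1e6,
              x$n_detection, x$detection_prf / 1e3),
      sprintf("  fast-time step %.1f us, measurement %.4f s, repeated every %.1f s for %.0f s\n",
              tm$fast_time_step * 1e6, tm$total, x$measurement_interval,
              x$total_duration))
  invisible(x)
}

#' Timing summary of a pulse sequence
#'
#' @param seq A [pulse_sequence()] object.
#' @return A list with `fast_time_step` (1/PRF), `baseline_span`,
#'   `push_duration` (`push_cycles / carrier_frequency`), `detection_span`
#'   and `total`, all in seconds.
#' @examples
#' sequence_timing(pulse_sequence())$total  # ~0.052 s, well under 0.5 s
#' @export
sequence_timing <- function(seq) {
  stopifnot(inherits(seq, "rar_sequence"))
  dtau <- 1 / seq$detection_prf
  push <- seq$push_cycles / seq$carrier_frequency
  list(
    fast_time_step = dtau,
    baseline_span = seq$n_baseline * dtau,
    push_duration = push,
    detection_span = seq$n_detection * dtau,
    total = seq$n_baseline * dtau + push + seq$n_detection * dtau
  )
}

#' Number of measurements in a run
#'
#' @param seq A [pulse_sequence()] object.
#' @return Integer count `total_duration / measurement_interval` (floored).
#' @export
n_measurements <- function(seq) {
  stopifnot(inherits(seq, "rar_sequence"))
  as.integer(floor(seq$total_duration / seq$measurement_interval + 1e-9))
}
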