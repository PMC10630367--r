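# Coagulation kinetics from the tracked resonant-frequency series f(T).
#
# The initial frequency f_int is the average over the first minute; the
# final frequency f_end is the average over the last five minutes.  Clotting
# starts (T_int) when f(T) first rises 5% above f_int and stays there for
# the next sample; it ends (T_end) when f(T) first reaches 95% of f_end,
# likewise sustained.  The clotting duration is T_end - T_int, and the
# final frequency converts to the shear modulus of the formed clot through
# the Rayleigh-wave inversion.

as_freq_series <- function(series) {
  if (inherits(series, "rar_freq_series") || is.data.frame(series)) {
    stopifnot(all(c("time", "frequency") %in% names(series)))
    df <- series
  } else stop("`series` must be a data frame with columns time, frequency",
              call. = FALSE)
  if (is.null(df$interpolated)) df$interpolated <- FALSE
  if (is.unsorted(df$time)) df <- df[order(df$time), ]
  df
}

#' Initial resonant frequency
#'
#' Mean frequency over the first minute of the run: samples with
#' `time <= min(time) + 60` (closed window; on a 6 s grid this is 11
#' samples). Masked/interpolated samples are excluded.
#'
#' @param series A [track_peak()] frequency series (columns `time`,
#'   `frequency`, optionally `interpolated`).
#' @return f_int in Hz.
#' @export
f_initial <- function(series) {
  df <- as_freq_series(series)
  if (max(df$time) - min(df$time) < 60)
    stop("series must span at least 60 s to define f_int", call. = FALSE)
  sel <- df$time <= min(df$time) + 60 & !df$interpolated &
    is.finite(df$frequency)
  if (!any(sel)) stop("no valid samples in the first minute", call. = FALSE)
  mean(df$frequency[sel])
}

#' Final resonant frequency
#'
#' Mean frequency over the last five minutes of the run: samples with
#' `time >= max(time) - 300` (closed window; 51 samples on a 6 s grid).
#' Masked/interpolated samples are excluded.
#'
#' @inheritParams f_initial
#' @return f_end in Hz.
#' @export
f_final <- function(series) {
  df <- as_freq_series(series)
  if (max(df$time) - min(df$time) < 300)
    stop("series must span at least 5 min to define f_end", call. = FALSE)
  sel <- df$time >= max(df$time) - 300 & !df$interpolated &
    is.finite(df$frequency)
  if (!any(sel)) stop("no valid samples in the last 5 min", call. = FALSE)
  mean(df$frequency[sel])
}

# Earliest time at which `frequency >= threshold` holds for `sustain`
# consecutive samples; NA_real_ sentinel when never sustained.
sustained_crossing <- function(time, frequency, threshold, sustain = 2L) {
  n <- length(frequency)
  sustain <- max(1L, as.integer(sustain))
  above <- is.finite(frequency) & frequency >= threshold
  if (sustain == 1L) {
    i <- which(above)[1L]
    return(if (is.na(i)) NA_real_ else time[i])
  }
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) return(time[i - sustain + 1L])
  }
  NA_real_
}

#' Clotting start time
#'
#' Earliest time at which the resonant frequency has risen by
#' `rise_fraction` (default 5%) above `f_int` and remains there for the
#' next consecutive sample — a single noisy sample does not trigger the
#' start. Returns the `NA` sentinel for a series that never rises
#' (non-clotting sample), never an error.
#'
#' @inheritParams f_initial
#' @param f_int Initial frequency in Hz (> 0), from [f_initial()].
#' @param rise_fraction Relative rise defining the start (default 0.05).
#' @param sustain Number of consecutive samples the crossing must hold
#'   (default 2).
#' @return T_int in seconds, or `NA_real_`.
#' @export
clotting_start <- function(series, f_int, rise_fraction = 0.05, sustain = 2L) {
  df <- as_freq_series(series)
  f_int <- check_scalar(f_int, "f_int", positive = TRUE)
  sustained_crossing(df$time, df$frequency, (1 + rise_fraction) * f_int,
                     sustain)
}

#' Clotting end time
#'
#' Earliest time at which the frequency reaches `end_fraction` (default
#' 95%) of `f_end`, sustained for the next consecutive sample, marking the
#' end of the active clotting process. For a constant series this is the
#' first sample (degenerate but well defined). `NA` sentinel when never
#' reached.
#'
#' @inheritParams clotting_start
#' @param f_end Final frequency in Hz (> 0), from [f_final()].
#' @param end_fraction Fraction of `f_end` defining the end (default 0.95).
#' @return T_end in seconds, or `NA_real_`.
#' @export
clotting_end <- function(series, f_end, end_fraction = 0.95, sustain = 2L) {
  df <- as_freq_series(series)
  f_end <- check_scalar(f_end, "f_end", positive = TRUE)
  sustained_crossing(df$time, df$frequency, end_fraction * f_end, sustain)
}

#' Extract coagulation parameters from a frequency series
#'
#' Composes [f_initial()], [f_final()], [clotting_start()] and
#' [clotting_end()]. A clot is detected when both the start and the end
#' crossing are found; only then are the clotting duration and the final
#' shear modulus (Rayleigh inversion of `f_end`) reported. Non-clotting
#' series yield sentinels, never errors: anticoagulated samples may
#' legitimately not clot within the observation window.
#'
#' Times are referenced to the first measurement (elapsed-time convention).
#' `time_offset` (e.g. a measured sample-preparation dead time) is added to
#' the reported `T_int`/`T_end` for users who want trigger-referenced times;
#' the default 0 reports measurement-referenced times.
#'
#' @inheritParams clotting_start
#' @param geometry Optional [well_geometry()]; enables the shear-modulus
#'   conversion of `f_end`.
#' @param rise_fraction,end_fraction,sustain Threshold-rule settings.
#' @param time_offset Seconds added to reported clotting times (default 0).
#' @return An object of class `rar_coag_params`: list with `f_int`, `f_end`
#'   (Hz), `T_int`, `T_end`, `duration` (s, `NA` sentinels when no clot),
#'   `final_shear_modulus` (Pa or `NA`), `clot_detected`, `channel`.
#' @export
extract_parameters <- function(series, geometry = NULL,
                               rise_fraction = 0.05, end_fraction = 0.95,
                               sustain = 2L, time_offset = 0) {
  df <- as_freq_series(series)
  f_int <- f_initial(df)
  f_end <- f_final(df)
  t_int <- clotting_start(df, f_int, rise_fraction, sustain)
  t_end <- clotting_end(df, f_end, end_fraction, sustain)
  detected <- !is.na(t_int) && !is.na(t_end)
  g_final <- NA_real_
  if (detected && !is.null(geometry))
    g_final <- invert_shear_modulus(f_end, geometry)
  structure(list(
    f_int = f_int, f_end = f_end,
    T_int = if (is.na(t_int)) NA_real_ else t_int + time_offset,
    T_end = if (is.na(t_end)) NA_real_ else t_end + time_offset,
    duration = if (detected) t_end - t_int else NA_real_,
    final_shear_modulus = g_final,
    clot_detected = detected,
    channel = attr(series, "channel") %||% NA_integer_
  ), class = "rar_coag_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rar_coag_params <- function(x, ...) {
  cat("Coagulation parameters:\n")
  cat(sprintf("  f_int = %.2f Hz, f_end = %.2f Hz\n", x$f_int, x$f_end))
  if (x$clot_detected) {
    cat(sprintf("  T_int = %.1f s, T_end = %.1f s, duration = %.1f s\n",
                x$T_int, x$T_end, x$duration))
    if (is.finite(x$final_shear_modulus))
      cat(sprintf("  final shear modulus = %.1f Pa\n", x$final_shear_modulus))
  } else cat("  no clot detected within the observation window\n")
  invisible(x)
}

#' Tidy parameter table for a set of channels
#'
#' One row per channel with the extracted coagulation parameters — the flat
#' export consumed by external statistics tools.
#'
#' @param params A list of [extract_parameters()] results (or a single one).
#' @param config_hash Optional provenance hash recorded in every row.
#' @return A data frame with columns `channel`, `f_int`, `f_end`, `T_int`,
#'   `T_end`, `duration`, `final_shear_modulus`, `clot_detected`,
#'   `config_hash`.
#' @export
parameters_table <- function(params, config_hash = NA_character_) {
  if (inherits(params, "rar_coag_params")) params <- list(params)
  rows <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    data.frame(
      channel = if (is.na(p$channel)) i else p$channel,
      f_int = p$f_int, f_end = p$f_end,
      T_int = p$T_int, T_end = p$T_end, duration = p$duration,
      final_shear_modulus = p$final_shear_modulus,
      clot_detected = p$clot_detected,
      config_hash = config_hash
    )
  })
  do.call(rbind, rows)
}
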