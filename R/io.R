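# Configuration, HDF5 container, pipeline orchestration and flat exports.
#
# Container layout (schema "rar-container-1"):
#   /meta                      group; attrs: schema_version, config_json,
#                              config_hash, seed
#   /channels/<i>              group; attrs: channel, seed, noise_snr_db
#     rf_baseline              n_baseline x L x M array (optional)
#     rf_detection             n_detection x L x M array (optional)
#     slow_times               M-vector (s)
#     truth                    group; trajectory fields as attrs (optional)
#     displacement             M x N matrix (m); attrs dT, dtau, sign
#     displacement_quality     M x N matrix
#     spectrogram/             power, normalized_power, frequencies,
#                              slow_times, peak_series, width_series, valid
#     parameters               group; extracted parameters as attrs
# Later groups are simply absent for partial pipelines.  Unknown extra
# top-level groups are read into $extra and written back untouched.

RAR_SCHEMA_VERSION <- "rar-container-1"

default_config <- function() {
  list(
    geometry = list(radius_m = 3.25e-3, mode_constant = 2.4048,
                    density_kg_m3 = 1000, sound_speed_m_s = 1480),
    sequence = list(n_baseline = 20, push_cycles = 100,
                    carrier_frequency_hz = 5.0e6, detection_prf_hz = 1.0e4,
                    n_detection = 500, sampling_rate_hz = 62.5e6,
                    measurement_interval_s = 6.0, total_duration_s = 3600),
    echo = list(surface_delay_s = 3.0e-6, pulse_duration_s = 0.6e-6,
                gate_length_s = 5.0e-6),
    simulate = list(noise_snr_db = 30, channels = list(
      as.list(unclass(coagulation_trajectory()))
    )),
    analysis = list(rise_fraction = 0.05, end_fraction = 0.95, sustain = 2,
                    smooth_window = 3, quality_floor = 0.5, pad_factor = 8,
                    max_lag = 16, time_offset_s = 0),
    seed = 1L
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run configuration
#'
#' Builds and validates the configuration driving every pipeline stage.
#' Accepts a named list of overrides, or a path to a YAML or JSON file with
#' the same structure; values not given fall back to the defaults (the
#' standard acquisition protocol and analysis thresholds). Validation
#' constructs the geometry, sequence and trajectory objects, so invalid
#' values fail here, before any stage runs.
#'
#' Top-level keys: `geometry` (`radius_m`, `mode_constant`,
#' `density_kg_m3`, `sound_speed_m_s`), `sequence` (protocol fields, Hz/s
#' units suffixed), `echo` (simulator gate), `simulate` (`noise_snr_db`,
#' `channels`: list of trajectory parameter lists), `analysis`
#' (`rise_fraction`, `end_fraction`, `sustain`, `smooth_window`,
#' `quality_floor`, `pad_factor`, `max_lag`, `time_offset_s`), `seed`.
#'
#' @param x Named list of overrides, a file path, or `NULL` for defaults.
#' @return A validated list of class `rar_config`.
#' @export
rar_config <- function(x = NULL) {
  if (inherits(x, "rar_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE))
      yaml::read_yaml(x)
    else jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a list or a YAML/JSON path",
                        call. = FALSE)
  cfg <- deep_merge(default_config(), x)
  cfg$seed <- check_count(cfg$seed, "seed", minimum = 0L)
  # validate by construction
  config_geometry(cfg)
  config_sequence(cfg)
  config_echo(cfg)
  lapply(cfg$simulate$channels, function(ch) do.call(coagulation_trajectory, ch))
  with(cfg$analysis, {
    check_scalar(rise_fraction, "analysis.rise_fraction", positive = TRUE)
    check_scalar(end_fraction, "analysis.end_fraction", positive = TRUE)
    check_scalar(quality_floor, "analysis.quality_floor", non_negative = TRUE)
  })
  structure(cfg, class = c("rar_config", "list"))
}

config_geometry <- function(cfg) {
  with(cfg$geometry, well_geometry(radius = radius_m,
                                   mode_constant = mode_constant,
                                   density = density_kg_m3,
                                   sound_speed = sound_speed_m_s))
}

config_sequence <- function(cfg) {
  with(cfg$sequence, pulse_sequence(
    n_baseline = n_baseline, push_cycles = push_cycles,
    carrier_frequency = carrier_frequency_hz, detection_prf = detection_prf_hz,
    n_detection = n_detection, sampling_rate = sampling_rate_hz,
    measurement_interval = measurement_interval_s,
    total_duration = total_duration_s))
}

config_echo <- function(cfg) {
  with(cfg$echo, echo_model(surface_delay = surface_delay_s,
                            pulse_duration = pulse_duration_s,
                            gate_length = gate_length_s))
}

# ---- container ------------------------------------------------------------

#' Assemble an in-memory container from a simulated plate
#'
#' @param plate A [simulate_plate()] result.
#' @param config The [rar_config()] that produced it.
#' @return An object of class `rar_container`.
#' @export
as_rar_container <- function(plate, config) {
  stopifnot(inherits(plate, "rar_plate"))
  config <- rar_config(config)
  channels <- lapply(plate$channels, function(ch) {
    list(channel = ch$channel, seed = ch$seed,
         noise_snr_db = ch$noise_snr_db, truth = ch$truth,
         rf = ch$measurements, displacement = NULL, spectrogram = NULL,
         parameters = NULL)
  })
  structure(list(
    meta = list(schema_version = RAR_SCHEMA_VERSION,
                config = unclass(config), config_hash = config_hash(config),
                seed = config$seed),
    sequence = plate$sequence, geometry = plate$geometry, echo = plate$echo,
    channels = channels, extra = list()
  ), class = "rar_container")
}

#' @export
print.rar_container <- function(x, ...) {
  stages <- vapply(x$channels, function(ch) {
    paste0(c("rf", "disp", "spec", "par")[c(!is.null(ch$rf),
                                            !is.null(ch$displacement),
                                            !is.null(ch$spectrogram),
                                            !is.null(ch$parameters))],
           collapse = "+")
  }, character(1))
  cat(sprintf("RAR container (%s): %d channels [%s], hash %s\n",
              x$meta$schema_version, length(x$channels),
              paste(stages, collapse = ", "),
              substr(x$meta$config_hash, 1, 8)))
  invisible(x)
}

h5_attrs <- function(loc, name, attrs) {
  obj <- rhdf5::H5Oopen(loc, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (is.null(v)) next
    rhdf5::h5writeAttribute(v, obj, nm)
  }
}

#' Write a container to HDF5
#'
#' Lossless serialization of all populated stages; absent stages leave
#' their groups absent. Unknown extra groups carried in `$extra` (from a
#' prior [read_rar()]) are written back untouched.
#'
#' @param container A `rar_container`.
#' @param path Output file path (overwritten).
#' @param include_rf Store the raw RF arrays (default `TRUE`; they dominate
#'   file size).
#' @return `path`, invisibly.
#' @export
write_rar <- function(container, path, include_rf = TRUE) {
  stopifnot(inherits(container, "rar_container"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  h5_attrs(fid, "meta", list(
    schema_version = container$meta$schema_version,
    config_json = as.character(canonical_json(container$meta$config)),
    config_hash = container$meta$config_hash,
    seed = container$meta$seed))
  rhdf5::H5Fclose(fid)

  rhdf5::h5createGroup(path, "channels")
  for (ch in container$channels) {
    g <- sprintf("channels/%d", ch$channel)
    rhdf5::h5createGroup(path, g)
    fid <- rhdf5::H5Fopen(path)
    h5_attrs(fid, g, list(channel = ch$channel, seed = ch$seed,
                          noise_snr_db = ch$noise_snr_db))
    rhdf5::H5Fclose(fid)

    if (!is.null(ch$rf) && include_rf) {
      base <- simplify2array(lapply(ch$rf, `[[`, "baseline"))
      det <- simplify2array(lapply(ch$rf, `[[`, "detection"))
      st <- vapply(ch$rf, `[[`, numeric(1), "slow_time")
      suppressMessages({  # rhdf5 chunk-size advisories on large arrays
        rhdf5::h5write(base, path, file.path(g, "rf_baseline"))
        rhdf5::h5write(det, path, file.path(g, "rf_detection"))
      })
      rhdf5::h5write(st, path, file.path(g, "slow_times"))
      fid <- rhdf5::H5Fopen(path)
      h5_attrs(fid, file.path(g, "rf_detection"), list(
        sampling_rate = container$sequence$sampling_rate, scale = 1.0,
        dtype = "float64"))
      rhdf5::H5Fclose(fid)
    }
    if (!is.null(ch$truth)) {
      tg <- file.path(g, "truth")
      rhdf5::h5createGroup(path, tg)
      fid <- rhdf5::H5Fopen(path)
      h5_attrs(fid, tg, unclass(ch$truth))
      rhdf5::H5Fclose(fid)
    }
    if (!is.null(ch$displacement)) {
      d <- ch$displacement
      rhdf5::h5write(d$matrix, path, file.path(g, "displacement"))
      rhdf5::h5write(d$quality, path, file.path(g, "displacement_quality"))
      rhdf5::h5write(d$slow_times, path, file.path(g, "displacement_slow_times"))
      fid <- rhdf5::H5Fopen(path)
      h5_attrs(fid, file.path(g, "displacement"), list(
        slow_time_step = d$slow_time_step, fast_time_step = d$fast_time_step,
        sign_convention = "positive = surface rising away from the transducer"))
      rhdf5::H5Fclose(fid)
    }
    if (!is.null(ch$spectrogram)) {
      s <- ch$spectrogram
      sg <- file.path(g, "spectrogram")
      rhdf5::h5createGroup(path, sg)
      rhdf5::h5write(s$power, path, file.path(sg, "power"))
      rhdf5::h5write(s$normalized_power, path, file.path(sg, "normalized_power"))
      rhdf5::h5write(s$frequencies, path, file.path(sg, "frequencies"))
      rhdf5::h5write(s$slow_times, path, file.path(sg, "slow_times"))
      rhdf5::h5write(s$peak_series, path, file.path(sg, "peak_series"))
      rhdf5::h5write(s$width_series, path, file.path(sg, "width_series"))
      rhdf5::h5write(as.integer(s$valid), path, file.path(sg, "valid"))
    }
    if (!is.null(ch$parameters)) {
      pg <- file.path(g, "parameters")
      rhdf5::h5createGroup(path, pg)
      p <- ch$parameters
      fid <- rhdf5::H5Fopen(path)
      h5_attrs(fid, pg, list(
        f_int = p$f_int, f_end = p$f_end, T_int = p$T_int, T_end = p$T_end,
        duration = p$duration, final_shear_modulus = p$final_shear_modulus,
        clot_detected = as.integer(p$clot_detected)))
      rhdf5::H5Fclose(fid)
    }
  }
  for (nm in names(container$extra)) {
    rhdf5::h5write(container$extra[[nm]], path, nm)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

read_truth <- function(path, name) {
  a <- rhdf5::h5readAttributes(path, name)
  do.call(coagulation_trajectory, lapply(a, as.numeric))
}

#' Read an HDF5 container
#'
#' Reconstructs the in-memory container, including geometry/sequence
#' objects from the embedded configuration. A schema-version mismatch is an
#' explicit error reporting both versions. Unrecognized top-level groups
#' are preserved in `$extra`.
#'
#' @param path Container file path.
#' @return A `rar_container`.
#' @export
read_rar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  meta <- rhdf5::h5readAttributes(path, "meta")
  if (!identical(as.character(meta$schema_version), RAR_SCHEMA_VERSION))
    stop(sprintf("container schema version %s; this build reads %s",
                 meta$schema_version, RAR_SCHEMA_VERSION), call. = FALSE)
  config <- rar_config(jsonlite::fromJSON(meta$config_json,
                                          simplifyDataFrame = FALSE))
  sequence <- config_sequence(config)
  geometry <- config_geometry(config)
  echo <- config_echo(config)

  ls_top <- rhdf5::h5ls(path, recursive = FALSE)
  ch_names <- rhdf5::h5ls(path, recursive = TRUE)
  ch_ids <- sort(as.integer(ch_names$name[ch_names$group == "/channels"]))
  channels <- lapply(ch_ids, function(i) {
    g <- sprintf("channels/%d", i)
    entries <- rhdf5::h5ls(path, recursive = TRUE)
    here <- entries$name[entries$group == paste0("/", g)]
    ga <- rhdf5::h5readAttributes(path, g)
    ch <- list(channel = as.integer(ga$channel), seed = as.integer(ga$seed),
               noise_snr_db = as.numeric(ga$noise_snr_db), truth = NULL,
               rf = NULL, displacement = NULL, spectrogram = NULL,
               parameters = NULL)
    if ("truth" %in% here) ch$truth <- read_truth(path, file.path(g, "truth"))
    if ("rf_detection" %in% here) {
      base <- rhdf5::h5read(path, file.path(g, "rf_baseline"))
      det <- rhdf5::h5read(path, file.path(g, "rf_detection"))
      st <- as.numeric(rhdf5::h5read(path, file.path(g, "slow_times")))
      ch$rf <- lapply(seq_along(st), function(m) {
        list(slow_time = st[m], baseline = base[, , m], detection = det[, , m])
      })
    }
    if ("displacement" %in% here) {
      da <- rhdf5::h5readAttributes(path, file.path(g, "displacement"))
      ch$displacement <- structure(list(
        matrix = rhdf5::h5read(path, file.path(g, "displacement")),
        quality = rhdf5::h5read(path, file.path(g, "displacement_quality")),
        slow_times = as.numeric(rhdf5::h5read(path, file.path(g, "displacement_slow_times"))),
        slow_time_step = as.numeric(da$slow_time_step),
        fast_time_step = as.numeric(da$fast_time_step),
        channel = as.integer(ga$channel)), class = "rar_matrix")
    }
    if ("spectrogram" %in% here) {
      sg <- file.path(g, "spectrogram")
      ch$spectrogram <- structure(list(
        slow_times = as.numeric(rhdf5::h5read(path, file.path(sg, "slow_times"))),
        frequencies = as.numeric(rhdf5::h5read(path, file.path(sg, "frequencies"))),
        normalized_power = rhdf5::h5read(path, file.path(sg, "normalized_power")),
        power = rhdf5::h5read(path, file.path(sg, "power")),
        peak_series = as.numeric(rhdf5::h5read(path, file.path(sg, "peak_series"))),
        width_series = as.numeric(rhdf5::h5read(path, file.path(sg, "width_series"))),
        valid = as.logical(rhdf5::h5read(path, file.path(sg, "valid"))),
        channel = as.integer(ga$channel)), class = "rar_spectrogram")
    }
    if ("parameters" %in% here) {
      pa <- rhdf5::h5readAttributes(path, file.path(g, "parameters"))
      ch$parameters <- structure(list(
        f_int = as.numeric(pa$f_int), f_end = as.numeric(pa$f_end),
        T_int = as.numeric(pa$T_int), T_end = as.numeric(pa$T_end),
        duration = as.numeric(pa$duration),
        final_shear_modulus = as.numeric(pa$final_shear_modulus),
        clot_detected = as.logical(pa$clot_detected),
        channel = as.integer(ga$channel)), class = "rar_coag_params")
    }
    ch
  })
  known <- c("meta", "channels")
  extra_names <- setdiff(ls_top$name, known)
  extra <- list()
  for (nm in extra_names) extra[[nm]] <- rhdf5::h5read(path, nm)

  structure(list(
    meta = list(schema_version = RAR_SCHEMA_VERSION,
                config = unclass(config),
                config_hash = as.character(meta$config_hash),
                seed = as.integer(meta$seed)),
    sequence = sequence, geometry = geometry, echo = echo,
    channels = channels, extra = extra
  ), class = "rar_container")
}

# ---- pipeline ---------------------------------------------------------------

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> displacement tracking -> spectral
#' analysis -> kinetics for every channel, logging per-stage timings.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config A [rar_config()] object, override list, or config path.
#' @param seed Optional seed overriding `config$seed`.
#' @param input Optional path to an existing container with RF data; when
#'   given, the simulate stage is skipped and tracking starts from the
#'   stored RF.
#' @param verbose Log stage timings and quality summaries (default `TRUE`).
#' @return A fully populated `rar_container`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, input = NULL,
                         verbose = TRUE) {
  config <- rar_config(config)
  if (!is.null(seed)) config$seed <- check_count(seed, "seed", minimum = 0L)
  sequence <- config_sequence(config)
  geometry <- config_geometry(config)
  echo <- config_echo(config)

  if (is.null(input)) {
    t0 <- proc.time()[3]
    trajectories <- lapply(config$simulate$channels,
                           function(ch) do.call(coagulation_trajectory, ch))
    plate <- simulate_plate(trajectories, sequence, geometry, echo,
                            noise_snr_db = config$simulate$noise_snr_db,
                            seed = config$seed)
    container <- as_rar_container(plate, config)
    stage_log(verbose, "[simulate] %d channels x %d measurements in %.1f s",
              length(container$channels),
              length(container$channels[[1]]$rf), proc.time()[3] - t0)
  } else {
    container <- read_rar(input)
    container$meta$config <- unclass(config)
    container$meta$config_hash <- config_hash(config)
  }

  an <- config$analysis
  for (i in seq_along(container$channels)) {
    ch <- container$channels[[i]]
    if (is.null(ch$rf))
      stop(sprintf("[track] channel %d has no RF data", ch$channel),
           call. = FALSE)
    chan_obj <- structure(list(sequence = sequence, geometry = geometry,
                               echo = echo, channel = ch$channel,
                               seed = ch$seed, truth = ch$truth,
                               noise_snr_db = ch$noise_snr_db,
                               measurements = ch$rf), class = "rar_channel")
    t0 <- proc.time()[3]
    dm <- build_matrix(chan_obj, max_lag = an$max_lag,
                       quality_floor = an$quality_floor)
    stage_log(verbose,
              "[track] channel %d: %d x %d matrix, median quality %.3f, %.1f s",
              ch$channel, nrow(dm$matrix), ncol(dm$matrix),
              median(dm$quality, na.rm = TRUE), proc.time()[3] - t0)
    t0 <- proc.time()[3]
    sg <- rar_spectrogram(dm, pad_factor = an$pad_factor)
    series <- track_peak(sg, smooth_window = an$smooth_window)
    attr(series, "channel") <- ch$channel
    stage_log(verbose, "[spectral] channel %d: %d/%d valid columns, %.1f s",
              ch$channel, sum(sg$valid), length(sg$valid),
              proc.time()[3] - t0)
    params <- extract_parameters(series, geometry,
                                 rise_fraction = an$rise_fraction,
                                 end_fraction = an$end_fraction,
                                 sustain = an$sustain,
                                 time_offset = an$time_offset_s)
    stage_log(verbose,
              "[kinetics] channel %d: f %.1f -> %.1f Hz, clot %s",
              ch$channel, params$f_int, params$f_end,
              if (params$clot_detected)
                sprintf("T_int %.0f s, T_end %.0f s", params$T_int,
                        params$T_end) else "not detected")
    container$channels[[i]]$displacement <- dm
    container$channels[[i]]$spectrogram <- sg
    container$channels[[i]]$frequency_series <- series
    container$channels[[i]]$parameters <- params
  }
  container
}

# ---- reports ----------------------------------------------------------------

#' Export flat reports and figures from a container
#'
#' Writes, for every populated stage: a parameter CSV (one row per
#' channel), a machine-readable JSON summary, and per-channel displacement
#' heatmaps and spectrogram images (fast time / frequency vertical, elapsed
#' time horizontal). Missing stages are skipped with a warning; partial
#' export is not an error.
#'
#' @param container A `rar_container`.
#' @param outdir Output directory (created if needed).
#' @param max_frequency Upper frequency limit of spectrogram figures, Hz.
#' @return Character vector of files written, invisibly.
#' @export
export_reports <- function(container, outdir, max_frequency = 1000) {
  stopifnot(inherits(container, "rar_container"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  params <- lapply(container$channels, `[[`, "parameters")
  have_params <- !vapply(params, is.null, logical(1))
  if (any(have_params)) {
    tab <- parameters_table(params[have_params],
                            config_hash = container$meta$config_hash)
    csv <- file.path(outdir, "parameters.csv")
    write.csv(format(tab, digits = 12, trim = TRUE), csv, row.names = FALSE,
              quote = FALSE)
    written <- c(written, csv)
    js <- file.path(outdir, "summary.json")
    jsonlite::write_json(list(
      schema_version = container$meta$schema_version,
      config_hash = container$meta$config_hash,
      seed = container$meta$seed,
      channels = lapply(params[have_params], unclass)
    ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, js)
  } else warning("no kinetics parameters in container; CSV/JSON skipped")

  pal <- hcl.colors(128, "viridis")
  for (ch in container$channels) {
    if (!is.null(ch$displacement)) {
      d <- ch$displacement
      fn <- file.path(outdir, sprintf("heatmap_ch%d.png", ch$channel))
      png(fn, width = 900, height = 500)
      tau_ms <- (seq_len(ncol(d$matrix)) - 1) * d$fast_time_step * 1e3
      image(d$slow_times, tau_ms, d$matrix * 1e6, col = pal,
            xlab = "elapsed time (s)", ylab = "fast time (ms)",
            main = sprintf("Surface displacement (um), channel %d",
                           ch$channel), useRaster = TRUE)
      dev.off()
      written <- c(written, fn)
    } else warning(sprintf("channel %d: no displacement; heatmap skipped",
                           ch$channel))
    if (!is.null(ch$spectrogram)) {
      s <- ch$spectrogram
      fn <- file.path(outdir, sprintf("spectrogram_ch%d.png", ch$channel))
      keep <- s$frequencies <= max_frequency
      png(fn, width = 900, height = 500)
      image(s$slow_times, s$frequencies[keep],
            t(s$normalized_power[keep, , drop = FALSE]), col = pal,
            xlab = "elapsed time (s)", ylab = "frequency (Hz)",
            main = sprintf("Normalized power spectrum, channel %d",
                           ch$channel), useRaster = TRUE)
      dev.off()
      written <- c(written, fn)
    } else warning(sprintf("channel %d: no spectrogram; figure skipped",
                           ch$channel))
  }
  invisible(written)
}
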