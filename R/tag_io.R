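# Deployment container and external formats.
#
# A deployment bundles the synchronized streams recorded by one tag:
# calibrated audio (stored in Pa), triaxial acceleration, depth, optional
# ECG, optional GPS fixes, and the exposure metadata. All stream time bases
# are seconds from deployment start.

#' Exposure metadata
#'
#' Describes one acoustic harassment device (AHD) exposure: when the source
#' transmitted, where it was, and its nominal output.
#'
#' @param exposure_start,exposure_end exposure window, seconds from
#'   deployment start.
#' @param ahd_lat,ahd_lon source position in decimal degrees.
#' @param source_level source level, dB re 1 uPa (rms) at 1 m.
#' @param ping_duration emitted ping duration, s.
#' @return an object of class `exposure_meta`.
#' @export
exposure_meta <- function(exposure_start, exposure_end, ahd_lat, ahd_lon,
                          source_level = 189, ping_duration = 0.5) {
  if (exposure_end <= exposure_start)
    stop("exposure_end must be after exposure_start")
  if (ping_duration <= 0) stop("ping_duration must be > 0")
  structure(list(exposure_start = exposure_start,
                 exposure_end = exposure_end,
                 ahd_lat = ahd_lat, ahd_lon = ahd_lon,
                 source_level = source_level,
                 ping_duration = ping_duration),
            class = "exposure_meta")
}

#' GPS fixes table
#'
#' @param time seconds from deployment start.
#' @param lat,lon decimal degrees.
#' @return data.frame of class `gps_fixes` with columns time, lat, lon.
#' @export
gps_fixes <- function(time, lat, lon) {
  if (is.unsorted(time, strictly = FALSE)) stop("GPS fixes must be time-ordered")
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) stop("invalid coordinates")
  structure(data.frame(time = time, lat = lat, lon = lon),
            class = c("gps_fixes", "data.frame"))
}

#' Assemble a sensor deployment
#'
#' Validates and bundles the streams from one tag record. Audio must already
#' be calibrated to pascal; [read_deployment()] does that conversion from a
#' WAV file plus its calibration sidecar.
#'
#' @param deployment_id character label.
#' @param audio list with `data` (numeric vector, Pa), `fs` (Hz) and
#'   `clip_db` (clip level, dB re 1 uPa).
#' @param accel list with `data` (n x 3 matrix, m/s^2) and `fs`.
#' @param depth list with `data` (numeric, m positive down) and `fs`.
#' @param ecg optional list with `data` (voltage, arbitrary units) and `fs`.
#' @param gps optional [gps_fixes()] table.
#' @param exposure an [exposure_meta()] object.
#' @return an object of class `sensor_deployment`.
#' @export
sensor_deployment <- function(deployment_id, audio, accel, depth,
                              ecg = NULL, gps = NULL, exposure = NULL) {
  for (s in list(audio, accel, depth, ecg)) {
    if (!is.null(s) && (is.null(s$fs) || s$fs <= 0))
      stop("all stream sampling rates must be > 0")
  }
  if (!is.null(audio) && !is.null(audio$clip_db)) {
    peak <- max(abs(audio$data))
    if (peak > db_to_pa(audio$clip_db) * (1 + 1e-6))
      stop("audio exceeds the stated clip level")
  }
  if (!is.null(depth) && any(depth$data < -0.5))
    stop("depth below -0.5 m is not physical")
  if (!is.null(accel) && ncol(accel$data) != 3)
    stop("accel$data must have 3 columns (x, y, z)")
  structure(list(deployment_id = deployment_id, audio = audio,
                 accel = accel, depth = depth, ecg = ecg, gps = gps,
                 exposure = exposure),
            class = "sensor_deployment")
}

#' @export
print.sensor_deployment <- function(x, ...) {
  cat("<sensor_deployment>", x$deployment_id, "\n")
  if (!is.null(x$audio))
    cat(sprintf("  audio: %.1f s @ %g Hz, clip %g dB re 1 uPa\n",
                length(x$audio$data) / x$audio$fs, x$audio$fs, x$audio$clip_db))
  cat(sprintf("  accel: %s; depth: %s%s%s\n",
              if (!is.null(x$accel)) sprintf("%g Hz", x$accel$fs) else "none",
              if (!is.null(x$depth)) sprintf("%g Hz", x$depth$fs) else "none",
              if (!is.null(x$ecg)) sprintf("; ecg: %g Hz", x$ecg$fs) else "",
              if (!is.null(x$gps)) sprintf("; gps: %d fixes", nrow(x$gps)) else ""))
  if (!is.null(x$exposure))
    cat(sprintf("  exposure: %.0f-%.0f s, SL %g dB re 1 uPa @ 1 m\n",
                x$exposure$exposure_start, x$exposure$exposure_end,
                x$exposure$source_level))
  invisible(x)
}

#' Read a tag deployment from disk
#'
#' Expects a WAV file, a sensors CSV (columns `time, ax, ay, az, depth` and
#' optionally `ecg`; lower-rate columns may be NA-padded between samples),
#' and a JSON calibration sidecar with at least `clip_level_db` and
#' `rates: {accel, depth [, ecg]}`, optionally `deployment_id`, `epoch_utc`,
#' an `exposure` block (`start, end, ahd_lat, ahd_lon, source_level,
#' ping_duration`) and `audio_channel`.
#'
#' Audio samples are converted to Pa so that a full-scale sample maps to the
#' clip-level pressure. For stereo recordings one channel is used (sidecar
#' `audio_channel`, default 1).
#'
#' @param audio_path WAV file.
#' @param sensors_path sensors CSV.
#' @param calib_path calibration JSON.
#' @param gps_path optional GPS CSV (columns `time, lat, lon`).
#' @return a [sensor_deployment()].
#' @export
read_deployment <- function(audio_path, sensors_path, calib_path,
                            gps_path = NULL) {
  calib <- jsonlite::read_json(calib_path, simplifyVector = TRUE)
  if (is.null(calib$clip_level_db)) stop("calibration sidecar lacks clip_level_db")
  wav <- read_wav(audio_path)
  ch <- calib$audio_channel %||% 1
  audio <- list(data = wav$samples[, ch] * db_to_pa(calib$clip_level_db),
                fs = wav$fs, clip_db = calib$clip_level_db)

  sens <- utils::read.csv(sensors_path)
  for (col in c("time", "ax", "ay", "az", "depth")) {
    if (!col %in% names(sens))
      stop("sensors CSV is missing required column '", col, "'")
  }
  rates <- calib$rates
  if (is.null(rates$accel) || rates$accel <= 0 ||
      is.null(rates$depth) || rates$depth <= 0)
    stop("calibration sidecar must give positive accel and depth rates")
  take <- function(cols, keep) {
    m <- as.matrix(sens[keep, cols, drop = FALSE])
    dimnames(m) <- NULL
    m
  }
  accel <- list(data = take(c("ax", "ay", "az"), !is.na(sens$ax)),
                fs = rates$accel)
  depth <- list(data = as.numeric(sens$depth[!is.na(sens$depth)]),
                fs = rates$depth)
  ecg <- NULL
  if ("ecg" %in% names(sens) && any(!is.na(sens$ecg))) {
    if (is.null(rates$ecg) || rates$ecg <= 0)
      stop("sensors CSV has an ecg column but the sidecar gives no ecg rate")
    ecg <- list(data = as.numeric(sens$ecg[!is.na(sens$ecg)]), fs = rates$ecg)
  }
  gps <- NULL
  if (!is.null(gps_path) && file.exists(gps_path)) {
    g <- utils::read.csv(gps_path)
    if (nrow(g) > 0) gps <- gps_fixes(g$time, g$lat, g$lon)
  }
  exposure <- NULL
  if (!is.null(calib$exposure)) {
    e <- calib$exposure
    exposure <- exposure_meta(e$start, e$end, e$ahd_lat, e$ahd_lon,
                              e$source_level, e$ping_duration)
  }
  sensor_deployment(calib$deployment_id %||% "deployment",
                    audio, accel, depth, ecg, gps, exposure)
}

#' Write a deployment to disk
#'
#' Inverse of [read_deployment()]: writes `audio.wav` (32-bit float, exact
#' round trip), `sensors.csv`, `calib.json` and, when GPS is present,
#' `gps.csv` into `dir`. Streams with different rates share one CSV: rows run
#' at the highest sensor rate and slower columns are NA between samples.
#'
#' @param dep a [sensor_deployment()].
#' @param dir output directory (created if needed).
#' @param audio_format passed to [write_wav()].
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(dep, dir, audio_format = "float") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wav(dep$audio$data / db_to_pa(dep$audio$clip_db), dep$audio$fs,
            file.path(dir, "audio.wav"), format = audio_format)

  streams <- list(accel = dep$accel, depth = dep$depth)
  if (!is.null(dep$ecg)) streams$ecg <- dep$ecg
  base_fs <- max(vapply(streams, function(s) s$fs, 0))
  n_len <- function(s) if (is.matrix(s$data)) nrow(s$data) else length(s$data)
  n_rows <- max(vapply(streams, function(s) ceiling(n_len(s) * base_fs / s$fs), 0))
  pad <- function(s, col) {
    out <- rep(NA_real_, n_rows)
    v <- if (is.matrix(s$data)) s$data[, col] else s$data
    idx <- round(seq_along(v) * base_fs / s$fs - base_fs / s$fs) + 1
    out[idx[idx <= n_rows]] <- v[idx <= n_rows]
    out
  }
  df <- data.frame(time = (seq_len(n_rows) - 1) / base_fs,
                   ax = pad(dep$accel, 1), ay = pad(dep$accel, 2),
                   az = pad(dep$accel, 3), depth = pad(dep$depth, 1))
  if (!is.null(dep$ecg)) df$ecg <- pad(dep$ecg, 1)
  utils::write.csv(df, file.path(dir, "sensors.csv"), row.names = FALSE)

  calib <- list(deployment_id = dep$deployment_id,
                clip_level_db = dep$audio$clip_db,
                rates = lapply(streams, function(s) s$fs))
  if (!is.null(dep$exposure)) {
    e <- dep$exposure
    calib$exposure <- list(start = e$exposure_start, end = e$exposure_end,
                           ahd_lat = e$ahd_lat, ahd_lon = e$ahd_lon,
                           source_level = e$source_level,
                           ping_duration = e$ping_duration)
  }
  jsonlite::write_json(calib, file.path(dir, "calib.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dep$gps)) {
    utils::write.csv(as.data.frame(dep$gps), file.path(dir, "gps.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Decimate a uniformly sampled series
#'
#' Anti-alias low-pass (zero-phase 4-pole Butterworth, cutoff 0.4 x the
#' target rate) followed by stride sampling. The decimation factor is the
#' nearest integer to `fs / target_rate`, so the achieved rate can differ
#' from `target_rate` by sample rounding; it is returned alongside the data.
#'
#' @param x numeric vector or matrix (columns decimated independently).
#' @param fs native sampling rate, Hz.
#' @param target_rate requested output rate, Hz (must be < `fs`).
#' @return list with `data` and `fs` (achieved rate).
#' @export
decimate_series <- function(x, fs, target_rate) {
  if (target_rate >= fs) stop("target_rate must be below the native rate")
  factor <- max(1L, as.integer(round(fs / target_rate)))
  out_fs <- fs / factor
  bf <- signal::butter(4, (0.4 * out_fs) / (fs / 2), type = "low")
  dec1 <- function(v) {
    zero_phase(bf, v)[seq(1, length(v), by = factor)]
  }
  data <- if (is.matrix(x)) apply(x, 2, dec1) else dec1(x)
  list(data = data, fs = out_fs)
}

#' Write timestamped event records to CSV
#'
#' @param events data.frame with a `time` column (written first).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (!"time" %in% names(events)) stop("events must have a 'time' column")
  if (nrow(events) > 1 && is.unsorted(events$time))
    stop("event times must be ordered")
  events <- events[, c("time", setdiff(names(events), "time")), drop = FALSE]
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an events CSV written by [write_events()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_events <- function(path) {
  utils::read.csv(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
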