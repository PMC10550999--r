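# Dive segmentation, apparent seafloor, visual crypsis and respirations.
#
# Visual crypsis is time spent within 2 m of the surface or of the apparent
# seafloor. Without bathymetry, the seafloor is inferred from U-shaped dives
# (long bottom phases close to the local bottom); with GPS and a bathymetry
# grid the grid depth is preferred. Respirations are broadband low-frequency
# transients on the tag audio while the animal is at the surface.

#' Segment dives from a depth series
#'
#' Maximal intervals with depth beyond `surface_threshold`. Shape is U when
#' the bottom phase (samples at >= 85% of max depth) occupies at least half
#' the dive, V when at most 20%, otherwise "other".
#'
#' @param depth list with `data` (m, positive down) and `fs` (>= 1 Hz), or a
#'   numeric vector with `fs` given.
#' @param fs sampling rate if `depth` is a bare vector.
#' @param surface_threshold m.
#' @return data.frame: start, end, max_depth, bottom_frac, shape.
#' @export
segment_dives <- function(depth, fs = NULL, surface_threshold = 0.5) {
  if (is.list(depth)) { fs <- depth$fs; depth <- depth$data }
  if (fs < 1) stop("depth rate must be >= 1 Hz")
  sub <- depth > surface_threshold
  if (!any(sub)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      max_depth = numeric(0), bottom_frac = numeric(0),
                      shape = character(0)))
  }
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- lapply(keep, function(i) {
    seg <- depth[starts[i]:ends[i]]
    md <- max(seg)
    bf <- mean(seg >= 0.85 * md)
    data.frame(start = (starts[i] - 1) / fs, end = ends[i] / fs,
               max_depth = md, bottom_frac = bf,
               shape = if (bf >= 0.5) "U" else if (bf <= 0.2) "V" else "other")
  })
  do.call(rbind, out)
}

#' Estimate the apparent seafloor depth over time
#'
#' With GPS fixes and a bathymetry grid (columns lat, lon, depth), the
#' nearest grid depth at each fix is interpolated over time. Otherwise the
#' max depths of U-shaped dives (assumed to reach close to the bottom) are
#' interpolated. Returns a function of time; its `available` attribute is
#' FALSE when neither source exists, in which case crypsis falls back to
#' surface-only.
#'
#' @param dives data.frame from [segment_dives()].
#' @param gps optional [gps_fixes()] table.
#' @param bathymetry optional data.frame with lat, lon, depth (m).
#' @return function(t) -> seafloor depth (m), with attribute `available`.
#' @export
estimate_seafloor <- function(dives, gps = NULL, bathymetry = NULL) {
  if (!is.null(bathymetry) && !is.null(gps) && nrow(gps) > 0) {
    d <- vapply(seq_len(nrow(gps)), function(i) {
      j <- which.min(geosphere::distGeo(cbind(bathymetry$lon, bathymetry$lat),
                                        c(gps$lon[i], gps$lat[i])))
      bathymetry$depth[j]
    }, 0)
    f <- if (nrow(gps) == 1) function(t) rep(d, length(t)) else
      stats::approxfun(gps$time, d, rule = 2)
    return(structure(f, available = TRUE, source = "bathymetry"))
  }
  u <- dives[dives$shape == "U", , drop = FALSE]
  if (nrow(u) == 0) {
    return(structure(function(t) rep(NA_real_, length(t)),
                     available = FALSE, source = "none"))
  }
  mid <- (u$start + u$end) / 2
  f <- if (nrow(u) == 1) function(t) rep(u$max_depth, length(t)) else
    stats::approxfun(mid, u$max_depth, rule = 2)
  structure(f, available = TRUE, source = "U-dives")
}

#' Visual crypsis mask and fraction
#'
#' Cryptic samples are within `margin` (2 m) of the surface or at/below
#' `seafloor - margin`. When the seafloor is unavailable only the surface
#' band counts.
#'
#' @param depth list with `data` and `fs`, or numeric vector with `fs`.
#' @param seafloor function of time (from [estimate_seafloor()]), a scalar
#'   depth, or `NULL`.
#' @param fs sampling rate if `depth` is a bare vector.
#' @param margin crypsis band, m.
#' @return list with `mask` (logical), `fs`, `times`.
#' @export
crypsis_mask <- function(depth, seafloor = NULL, fs = NULL, margin = 2) {
  if (is.list(depth)) { fs <- depth$fs; depth <- depth$data }
  times <- (seq_along(depth) - 1) / fs
  sf <- if (is.null(seafloor)) rep(NA_real_, length(depth))
  else if (is.function(seafloor)) {
    if (isFALSE(attr(seafloor, "available"))) rep(NA_real_, length(depth))
    else seafloor(times)
  } else rep(seafloor, length(depth))
  mask <- depth <= margin | (!is.na(sf) & depth >= sf - margin)
  list(mask = mask, fs = fs, times = times)
}

#' Fraction of time in crypsis over a window
#'
#' @param mask list from [crypsis_mask()].
#' @param window length-2 interval, s.
#' @return fraction in `[0, 1]`.
#' @export
crypsis_fraction <- function(mask, window) {
  sel <- mask$times >= window[1] & mask$times < window[2]
  if (!any(sel)) return(NA_real_)
  mean(mask$mask[sel])
}

#' Detect respirations on tag audio
#'
#' Surface exhalations ("blows") are broadband low-frequency transients.
#' The audio is decimated to a working rate, band-passed to 0.1-5 kHz, and
#' envelope peaks above the envelope median + `threshold_db` are kept when
#' the animal is near the surface (depth <= `max_depth`), at least `min_gap`
#' apart. Manual marks can replace the detector wherever respiration times
#' are consumed.
#'
#' @param audio list with `data` (Pa) and `fs`.
#' @param depth list with `data` (m) and `fs`.
#' @param band detection band, Hz.
#' @param threshold_db dB above the envelope median.
#' @param min_gap s.
#' @param max_depth depth gate, m.
#' @return data.frame: time, iri_prev (s since previous breath; NA first).
#' @export
detect_respirations <- function(audio, depth, band = c(100, 4000),
                                threshold_db = 12, min_gap = 2,
                                max_depth = 1) {
  # working rate keeps the 14-kHz AHD ping far above the anti-alias cutoff,
  # so ping energy cannot fold into the blow band
  work_fs <- 3 * band[2]
  x <- if (audio$fs > work_fs) {
    dec <- decimate_series(audio$data, audio$fs, work_fs)
    work_fs <- dec$fs
    dec$data
  } else {
    work_fs <- audio$fs
    audio$data
  }
  bf <- signal::butter(2, band / (work_fs / 2), type = "pass")
  xb <- zero_phase(bf, x)
  k <- max(2, round(0.05 * work_fs))
  env <- sqrt(moving_sum(xb^2, k) / k)
  thr <- stats::median(env[seq(1, length(env), by = max(1, length(env) %/% 1000000))]) *
    10^(threshold_db / 20)
  above <- env > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  dt <- (seq_along(depth$data) - 1) / depth$fs
  times <- numeric(0)
  last <- -Inf
  for (r in rises) {
    t0 <- (r - 1) / work_fs
    if (t0 - last < min_gap) next
    d_here <- depth$data[max(1, min(length(depth$data),
                                    round(t0 * depth$fs) + 1))]
    if (d_here <= max_depth) {
      times <- c(times, t0)
      last <- t0
    }
  }
  data.frame(time = times,
             iri_prev = if (length(times) > 0) c(NA, diff(times))
             else numeric(0))
}

#' Respiration rate over a window
#'
#' @param times breath times, s.
#' @param window length-2 interval, s.
#' @return breaths per minute.
#' @export
respiration_rate <- function(times, window) {
  len <- window[2] - window[1]
  if (len <= 0) stop("window length must be > 0")
  sum(times >= window[1] & times < window[2]) / (len / 60)
}
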