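# Acoustic propagation and GPS track kinematics.
#
# Received level falls off with range following an idealised spreading law
# plus linear absorption: TL(R) = k log10(R) + alpha R / 1000, with k = 20
# (spherical) or 10 (cylindrical) and alpha in dB/km. The tagged porpoises'
# RL-vs-range data were well described by spherical spreading with a medium
# absorption of 1.5 dB/km, and the mitigation arithmetic (impact radii, area
# ratios) follows from inverting this transmission loss.

#' Define a propagation model
#'
#' @param spreading `"spherical"` (20 log10 R) or `"cylindrical"`
#'   (10 log10 R).
#' @param absorption linear absorption, dB/km (>= 0). 1.5 dB/km is a typical
#'   mid-frequency value for temperate shelf waters at 14 kHz.
#' @return object of class `propagation_model`.
#' @export
propagation_model <- function(spreading = c("spherical", "cylindrical"),
                              absorption = 1.5) {
  spreading <- match.arg(spreading)
  if (absorption < 0) stop("absorption must be >= 0")
  structure(list(spreading = spreading,
                 coef = if (spreading == "spherical") 20 else 10,
                 absorption = absorption),
            class = "propagation_model")
}

#' Transmission loss at range
#'
#' `TL(R) = coef * log10(R) + absorption * R / 1000`, zero at 1 m.
#'
#' @param range range in metres (>= 1).
#' @param model a [propagation_model()].
#' @return TL in dB.
#' @export
transmission_loss <- function(range, model = propagation_model()) {
  if (any(range < 1)) stop("range must be >= 1 m (TL reference is 1 m)")
  model$coef * log10(range) + model$absorption * range / 1000
}

#' Received level at range from a source level
#'
#' @param sl source level, dB re 1 uPa (rms) at 1 m.
#' @param range range in metres.
#' @param model a [propagation_model()].
#' @return RL in dB re 1 uPa.
#' @export
received_level <- function(sl, range, model = propagation_model()) {
  sl - transmission_loss(range, model)
}

#' Solve for the range at which RL equals a threshold
#'
#' Inverts the monotone transmission loss by root bracketing. Used for
#' effect-range and impact-zone what-ifs (e.g. the range at which an AHD
#' ping falls to the behavioural response threshold).
#'
#' @param sl source level, dB re 1 uPa at 1 m.
#' @param rl_threshold the received level to solve for (must be < `sl`).
#' @param model a [propagation_model()].
#' @param bracket search interval in metres.
#' @return range in metres; `NA` with attribute `overflow = TRUE` when the
#'   threshold is not reached inside the bracket.
#' @export
solve_effect_range <- function(sl, rl_threshold, model = propagation_model(),
                               bracket = c(1, 1e5)) {
  if (sl <= rl_threshold) stop("sl must exceed rl_threshold")
  target <- sl - rl_threshold
  f <- function(r) transmission_loss(r, model) - target
  if (f(bracket[2]) < 0 || f(bracket[1]) > 0) {
    return(structure(NA_real_, overflow = TRUE))
  }
  stats::uniroot(f, interval = bracket, tol = 1e-4)$root
}

#' Ratio of two circular impact areas
#'
#' `(r1 / r2)^2`: how many times larger the area of radius `r1` is than that
#' of radius `r2` (A = pi r^2).
#'
#' @param r1,r2 radii (same unit), > 0.
#' @return dimensionless ratio.
#' @export
impact_area_ratio <- function(r1, r2) {
  if (any(c(r1, r2) <= 0)) stop("radii must be > 0")
  (r1 / r2)^2
}

#' Predicted behavioural response threshold
#'
#' Porpoises respond behaviourally at roughly a fixed sensation level above
#' their audiogram; at 14 kHz the hearing threshold is ~50 dB re 1 uPa and
#' the meta-analytic sensation level ~45 dB, predicting responses at ~95 dB
#' re 1 uPa rms.
#'
#' @param hearing_threshold dB re 1 uPa.
#' @param sensation_level dB above the hearing threshold.
#' @return predicted response threshold, dB re 1 uPa.
#' @export
response_threshold <- function(hearing_threshold = 50, sensation_level = 45) {
  hearing_threshold + sensation_level
}

#' Geodesic range from a position to the source
#'
#' @param lat,lon animal position(s), decimal degrees.
#' @param source_lat,source_lon source position.
#' @return range(s) in metres.
#' @export
range_to_source <- function(lat, lon, source_lat, source_lon) {
  geosphere::distGeo(cbind(lon, lat), c(source_lon, source_lat))
}

#' Per-leg horizontal travel speeds from GPS fixes
#'
#' Speed of each leg is geodesic distance over elapsed time. Legs faster
#' than `max_speed` are treated as erroneous fixes: the later fix of the
#' first offending leg is dropped and speeds recomputed across the gap,
#' iterating until no leg exceeds the limit. A centred running 5-sample mean
#' of the retained leg speeds is attached.
#'
#' @param fixes a [gps_fixes()] table (or data.frame with time, lat, lon).
#' @param max_speed exclusion threshold, m/s (default 5, well above porpoise
#'   top speed).
#' @param smooth running-mean window in samples.
#' @return object of class `track_estimate`: list with `fixes` (with an
#'   `excluded` flag), `legs` (t0, t1, dist, speed) over retained fixes, and
#'   `smoothed` speeds aligned with `legs`.
#' @export
leg_speeds <- function(fixes, max_speed = 5, smooth = 5) {
  if (nrow(fixes) < 2) stop("need at least 2 fixes")
  if (anyDuplicated(fixes$time)) stop("duplicate fix timestamps")
  fixes$excluded <- FALSE
  repeat {
    keep <- which(!fixes$excluded)
    if (length(keep) < 2) break
    k <- fixes[keep, ]
    d <- geosphere::distGeo(cbind(k$lon[-nrow(k)], k$lat[-nrow(k)]),
                            cbind(k$lon[-1], k$lat[-1]))
    sp <- d / diff(k$time)
    bad <- which(sp > max_speed)
    if (length(bad) == 0) break
    fixes$excluded[keep[bad[1] + 1]] <- TRUE
  }
  k <- fixes[!fixes$excluded, ]
  d <- geosphere::distGeo(cbind(k$lon[-nrow(k)], k$lat[-nrow(k)]),
                          cbind(k$lon[-1], k$lat[-1]))
  legs <- data.frame(t0 = k$time[-nrow(k)], t1 = k$time[-1], dist = d,
                     speed = d / diff(k$time))
  smoothed <- if (nrow(legs) >= smooth) {
    as.numeric(zoo::rollmean(zoo::zoo(legs$speed), smooth, fill = NA))
  } else rep(NA_real_, nrow(legs))
  structure(list(fixes = fixes, legs = legs, smoothed = smoothed),
            class = "track_estimate")
}

#' Median received level against range
#'
#' For each retained GPS fix, the median rms-fast RL of the `k` accepted
#' pings nearest in time is paired with the geodesic range to the source at
#' that fix, giving the empirical RL-vs-range profile that spreading models
#' are fitted against.
#'
#' @param pings data.frame of ping detections (needs `time`, `rl_rms_fast`,
#'   `accepted`).
#' @param track a [leg_speeds()] result or a [gps_fixes()] table.
#' @param source_lat,source_lon AHD position.
#' @param k number of nearest-in-time pings per fix.
#' @return data.frame: time, range, rl_median, n_pings, flagged (TRUE when
#'   fewer than `k` accepted pings were available).
#' @export
rl_vs_range_profile <- function(pings, track, source_lat, source_lon, k = 5) {
  fixes <- if (inherits(track, "track_estimate")) {
    track$fixes[!track$fixes$excluded, ]
  } else as.data.frame(track)
  acc <- pings[pings$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted pings")
  flagged <- nrow(acc) < k
  out <- lapply(seq_len(nrow(fixes)), function(i) {
    rng <- range_to_source(fixes$lat[i], fixes$lon[i], source_lat, source_lon)
    nearest <- order(abs(acc$time - fixes$time[i]))[seq_len(min(k, nrow(acc)))]
    data.frame(time = fixes$time[i], range = rng,
               rl_median = stats::median(acc$rl_rms_fast[nearest]),
               n_pings = length(nearest), flagged = flagged)
  })
  do.call(rbind, out)
}

#' Theil-Sen robust slope
#'
#' Median of all pairwise slopes; resistant to occasional outlying points.
#' Used for the RL-vs-time flight trend.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return slope in units of y per unit x.
#' @export
theil_sen_slope <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  stats::median(dy[ok] / dx[ok])
}
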