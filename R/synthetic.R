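# Synthetic tag deployments with full ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: an AHD emitting 500-ms 14-kHz pings (harmonics at 28 and 42 kHz)
# at randomized intervals, received on the tag at a level set by the
# animal-to-source range through a configurable propagation model;
# narrow-band high-frequency (~130 kHz) echolocation clicks and buzzes;
# fluking and startle-flinch acceleration; dive cycles over a seafloor with
# a programmable crypsis fraction; surface respiration transients; ECG with
# a programmed instantaneous heart-rate schedule; and a GPS track
# subsampled from the true movement. Every generated event is logged in a
# ground-truth object so detector recovery can be measured exactly.
#
# Schedule fields marked "per phase" accept a scalar (all phases), a length-2
# vector (pre-exposure, exposure-and-after) or a length-3 vector
# (pre, exposure, post).

#' Build a scenario configuration
#'
#' All arguments have defaults describing a single 14-kHz AHD exposure of a
#' porpoise-like animal. See the package vignette for the reasoning behind
#' each default.
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param duration record length, s.
#' @param exposure_start,exposure_end AHD transmission window, s.
#' @param audio_fs audio sampling rate, Hz (tags record 240-576 kHz).
#' @param accel_fs,depth_fs accelerometer and depth rates, Hz.
#' @param ahd list: `source_level` (dB re 1 uPa rms @ 1 m), `ping_duration`
#'   (s), `base_freq` (Hz), `harmonics` (Hz), `harmonic_levels` (dB rel.
#'   fundamental), `interval_range` (s, uniform), `ramp` (s, cosine on/off),
#'   `reverb` (logical) and `reverb_tau` (s).
#' @param propagation a [propagation_model()] used for true received levels.
#' @param position list: `ahd_lat`, `ahd_lon`, `start_range` (m, initial
#'   animal-source range), `sound_speed` (m/s).
#' @param track list: `speed` (m/s, per phase), `heading` (deg, per phase;
#'   180 = directly away from a source due north of the animal).
#' @param dive list: `cycle_period` (s), `seafloor_depth` (m),
#'   `crypsis_frac` (per phase; target fraction of time within 2 m of
#'   surface or seafloor), `surface_frac` (fraction of cycle at surface),
#'   `surface_depth` (m).
#' @param clicks list: `rate_cpm` (per phase), `level_pp` (dB re 1 uPa pp,
#'   per phase), `level_sd` (dB), `center_freq` (Hz), `sigma` (s, Gaussian
#'   envelope), `buzz_rate_per_min` (per phase), `buzz_ici` (s), `buzz_n`,
#'   `buzz_level_pp`, `buzz_jerk` (m/s^2 flinch coupled to each buzz),
#'   `social_runs` (count of buzz-like click runs with no jerk transient,
#'   placed in the pre phase).
#' @param startle list: `enabled`, `latency` (s after ping arrival),
#'   `amplitude` (m/s^2 per flinch), `flinch_duration` (s), `pings`
#'   (indices of pings that trigger a flinch).
#' @param fluking list: `freq` (Hz), `coef` (m/s^2 per m/s of speed),
#'   `amp` (optional per-phase override, m/s^2), `noise_sd` (m/s^2).
#' @param fh list: `schedule` (data.frame time, bpm; piecewise linear),
#'   `ecg_fs`, `noise_sd`.
#' @param respiration list: `rate` (breaths/min, per phase; breaths are
#'   placed deterministically within surface intervals), `level_db`
#'   (band level of the blow transient, dB re 1 uPa), `blow_duration` (s).
#' @param noise list: `level_db` (broadband flow-noise rms, dB re 1 uPa).
#' @param gps list: `fix_interval` (s, uniform range), `sigma` (m).
#' @param clip_db audio clip level, dB re 1 uPa.
#' @param streams which streams to synthesize; subset of
#'   `c("audio", "accel", "depth", "ecg", "gps")`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            duration = 120,
                            exposure_start = duration / 2,
                            exposure_end = duration,
                            audio_fs = 500000,
                            accel_fs = 200,
                            depth_fs = 50,
                            ahd = list(),
                            propagation = propagation_model(),
                            position = list(),
                            track = list(),
                            dive = list(),
                            clicks = list(),
                            startle = list(),
                            fluking = list(),
                            fh = list(),
                            respiration = list(),
                            noise = list(),
                            gps = list(),
                            clip_db = 175,
                            streams = c("audio", "accel", "depth", "gps")) {
  merge_defaults <- function(given, defaults) {
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    seed = seed, duration = duration,
    exposure_start = exposure_start, exposure_end = exposure_end,
    audio_fs = audio_fs, accel_fs = accel_fs, depth_fs = depth_fs,
    ahd = merge_defaults(ahd, list(
      source_level = 189, ping_duration = 0.5, base_freq = 14000,
      harmonics = c(28000, 42000), harmonic_levels = c(-20, -30),
      interval_range = c(0.6, 90), ramp = 0.005,
      reverb = FALSE, reverb_tau = 0.2)),
    propagation = propagation,
    position = merge_defaults(position, list(
      ahd_lat = 56.0, ahd_lon = 10.5, start_range = 1000,
      sound_speed = 1500)),
    track = merge_defaults(track, list(speed = 1.5, heading = 180)),
    dive = merge_defaults(dive, list(
      cycle_period = 60, seafloor_depth = 25, crypsis_frac = 0.7,
      surface_frac = 0.25, surface_depth = 0.3)),
    clicks = merge_defaults(clicks, list(
      rate_cpm = 60, level_pp = 150, level_sd = 0.5, center_freq = 130000,
      sigma = 10e-6, buzz_rate_per_min = 0, buzz_ici = 0.005, buzz_n = 25,
      buzz_level_pp = 140, buzz_jerk = 1.5, social_runs = 0)),
    startle = merge_defaults(startle, list(
      enabled = TRUE, latency = 0.1, amplitude = 4,
      flinch_duration = 0.12, pings = 1:3)),
    fluking = merge_defaults(fluking, list(
      freq = 1.4, coef = 0.8, amp = NULL, noise_sd = 0.05)),
    fh = merge_defaults(fh, list(
      schedule = data.frame(time = 0, bpm = 80), ecg_fs = 5000,
      noise_sd = 0.02)),
    respiration = merge_defaults(respiration, list(
      rate = 3.5, level_db = 100, blow_duration = 0.3)),
    noise = merge_defaults(noise, list(level_db = 85)),
    gps = merge_defaults(gps, list(fix_interval = c(180, 300), sigma = 5)),
    clip_db = clip_db, streams = streams)
  if (cfg$exposure_end <= cfg$exposure_start)
    stop("exposure_end must be after exposure_start")
  if (cfg$duration < cfg$exposure_end)
    stop("duration must cover the exposure window")
  if (any(cfg$ahd$interval_range <= 0) || any(unlist(cfg$clicks[c(
    "rate_cpm", "buzz_rate_per_min")]) < 0))
    stop("rates must be >= 0 and ping intervals > 0")
  if ((cfg$exposure_end - cfg$exposure_start) < cfg$ahd$ping_duration)
    stop("exposure window too short for a single ping")
  structure(cfg, class = "scenario_config")
}

# expand a per-phase schedule value to length 3 (pre, exposure, post)
phase_vec <- function(v) {
  if (length(v) == 1) rep(v, 3)
  else if (length(v) == 2) c(v[1], v[2], v[2])
  else v[1:3]
}

# phase index (1 pre, 2 exposure, 3 post) for times t
phase_of <- function(t, es, ee) 1L + (t >= es) + (t >= ee)

# local east/north metres -> lat/lon around the AHD position
enu_to_latlon <- function(x, y, lat0, lon0) {
  list(lat = lat0 + y / 111320,
       lon = lon0 + x / (111320 * cos(lat0 * pi / 180)))
}

#' Generate a synthetic deployment with ground truth
#'
#' @param config a [scenario_config()].
#' @return list with `deployment` (a [sensor_deployment()]) and `truth`
#'   (class `ground_truth`): `pings` (emit/arrival times, true range, RL,
#'   single-ping SEL), `clicks` (time, level, buzz id), `buzzes`,
#'   `social_runs`, `startle_times`, `respiration_times`, `r_times`,
#'   `track` (1-Hz true positions, speeds, ranges), `crypsis` (true mask at
#'   the depth rate), `seafloor_depth` and the config.
#' @export
generate_deployment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  cfg <- config
  es <- cfg$exposure_start; ee <- cfg$exposure_end
  dur <- cfg$duration

  ## --- true track (1 Hz) -------------------------------------------------
  tg <- 0:floor(dur)
  ph <- phase_of(tg, es, ee)
  sp <- phase_vec(cfg$track$speed)[ph]
  hd <- phase_vec(cfg$track$heading)[ph] * pi / 180
  vx <- sp * sin(hd); vy <- sp * cos(hd)
  x <- 0 + cumsum(c(0, vx[-length(vx)]))
  y <- -cfg$position$start_range + cumsum(c(0, vy[-length(vy)]))
  rng <- sqrt(x^2 + y^2)
  ll <- enu_to_latlon(x, y, cfg$position$ahd_lat, cfg$position$ahd_lon)
  track <- data.frame(time = tg, x = x, y = y, lat = ll$lat, lon = ll$lon,
                      speed = sp, range = rng)
  range_at <- stats::approxfun(tg, rng, rule = 2)

  ## --- ping schedule and true dosimetry ----------------------------------
  ir <- cfg$ahd$interval_range
  emit <- es
  repeat {
    nxt <- emit[length(emit)] + stats::runif(1, ir[1], ir[2])
    if (nxt > ee - cfg$ahd$ping_duration) break
    emit <- c(emit, nxt)
  }
  r_emit <- pmax(range_at(emit), 1)
  arrival <- emit + r_emit / cfg$position$sound_speed
  rl_true <- received_level(cfg$ahd$source_level, r_emit, cfg$propagation)

  ## --- depth -------------------------------------------------------------
  depth <- NULL; crypsis_true <- NULL
  sf_depth <- cfg$dive$seafloor_depth
  bottom <- sf_depth - 1
  surf_d <- cfg$dive$surface_depth
  if ("depth" %in% cfg$streams) {
    nd <- floor(dur * cfg$depth_fs)
    td <- (seq_len(nd) - 1) / cfg$depth_fs
    cyc <- cfg$dive$cycle_period
    cf <- phase_vec(cfg$dive$crypsis_frac)
    sfr <- cfg$dive$surface_frac
    # share of a linear transit spent inside the 2-m crypsis bands
    k <- ((2 - surf_d) + 1) / (bottom - surf_d)
    dphase <- phase_of(td, es, ee)
    tau <- ((td - c(0, es, ee)[dphase]) %% cyc) / cyc
    dep <- numeric(nd)
    for (p in 1:3) {
      # bottom fraction of the dive needed to hit the target crypsis
      bf <- ((cf[p] - sfr) / (1 - sfr) - k) / (1 - k)
      bf <- min(max(bf, 0.05), 0.9)
      tr <- (1 - sfr - (1 - sfr) * bf) / 2          # each transit leg
      bstart <- sfr + tr; bend <- 1 - tr
      sel <- dphase == p
      u <- tau[sel]
      d <- numeric(sum(sel)) + surf_d
      desc <- u > sfr & u < bstart
      d[desc] <- surf_d + (bottom - surf_d) * (u[desc] - sfr) / tr
      d[u >= bstart & u <= bend] <- bottom
      asc <- u > bend
      d[asc] <- bottom - (bottom - surf_d) * (u[asc] - bend) / tr
      dep[sel] <- d
    }
    depth <- list(data = dep, fs = cfg$depth_fs)
    crypsis_true <- list(mask = dep <= 2 | dep >= sf_depth - 2,
                         fs = cfg$depth_fs)
  }

  ## --- respiration times (deterministic within surface intervals) --------
  resp_times <- numeric(0)
  if (!is.null(depth)) {
    rrate <- phase_vec(cfg$respiration$rate)
    td <- (seq_along(depth$data) - 1) / depth$fs
    bounds <- list(c(0, es), c(es, ee), c(ee, dur))
    for (p in 1:3) {
      len <- bounds[[p]][2] - bounds[[p]][1]
      n <- round(rrate[p] * len / 60)
      if (n <= 0) next
      at_surf <- which(depth$data <= 0.5 & td >= bounds[[p]][1] &
                         td < bounds[[p]][2])
      if (length(at_surf) < n) at_surf <- which(td >= bounds[[p]][1] &
                                                  td < bounds[[p]][2])
      pick <- at_surf[pmax(1, round(seq(0.5, n - 0.5, by = 1) / n *
                                      length(at_surf)))]
      resp_times <- c(resp_times, td[pick])
    }
    resp_times <- sort(resp_times)
  }

  ## --- echolocation click schedule ---------------------------------------
  click_df <- data.frame(time = numeric(0), level_pp = numeric(0),
                         buzz = integer(0))
  buzz_df <- data.frame(start = numeric(0), end = numeric(0),
                        n_clicks = integer(0))
  social_df <- buzz_df
  cl <- cfg$clicks
  rate3 <- phase_vec(cl$rate_cpm); lev3 <- phase_vec(cl$level_pp)
  brate3 <- phase_vec(cl$buzz_rate_per_min)
  bounds <- list(c(0, es), c(es, ee), c(ee, dur))
  for (p in 1:3) {
    len <- bounds[[p]][2] - bounds[[p]][1]
    lam <- rate3[p] / 60
    if (lam > 0 && len > 0) {
      n <- stats::rpois(1, lam * len)
      if (n > 0) {
        tt <- sort(stats::runif(n, bounds[[p]][1], bounds[[p]][2]))
        click_df <- rbind(click_df, data.frame(
          time = tt, level_pp = lev3[p] + stats::rnorm(n, 0, cl$level_sd),
          buzz = NA_integer_))
      }
    }
    nb <- stats::rpois(1, brate3[p] / 60 * len)
    if (nb > 0) {
      bstarts <- sort(stats::runif(nb, bounds[[p]][1],
                                   bounds[[p]][2] - cl$buzz_n * cl$buzz_ici))
      for (b in bstarts) {
        id <- nrow(buzz_df) + 1L
        tt <- b + (0:(cl$buzz_n - 1)) * cl$buzz_ici
        click_df <- rbind(click_df, data.frame(
          time = tt, level_pp = cl$buzz_level_pp, buzz = id))
        buzz_df <- rbind(buzz_df, data.frame(
          start = b, end = max(tt), n_clicks = cl$buzz_n))
      }
    }
  }
  if (cl$social_runs > 0) {
    # buzz-like ICI runs with no accompanying jerk transient (social calls)
    sstarts <- seq(2, es - cl$buzz_n * cl$buzz_ici - 2,
                   length.out = cl$social_runs)
    for (b in sstarts) {
      tt <- b + (0:(cl$buzz_n - 1)) * cl$buzz_ici
      click_df <- rbind(click_df, data.frame(
        time = tt, level_pp = cl$buzz_level_pp, buzz = NA_integer_))
      social_df <- rbind(social_df, data.frame(
        start = b, end = max(tt), n_clicks = cl$buzz_n))
    }
  }
  click_df <- click_df[order(click_df$time), ]

  ## --- acceleration -------------------------------------------------------
  accel <- NULL
  startle_times <- numeric(0)
  if (cfg$startle$enabled && length(emit) > 0) {
    hit <- cfg$startle$pings[cfg$startle$pings <= length(arrival)]
    startle_times <- arrival[hit] + cfg$startle$latency
  }
  if ("accel" %in% cfg$streams) {
    na <- floor(dur * cfg$accel_fs)
    ta <- (seq_len(na) - 1) / cfg$accel_fs
    aph <- phase_of(ta, es, ee)
    amp <- if (!is.null(cfg$fluking$amp)) {
      phase_vec(cfg$fluking$amp)[aph]
    } else cfg$fluking$coef * phase_vec(cfg$track$speed)[aph]
    w <- 2 * pi * cfg$fluking$freq * ta
    ax <- 0.3 * amp * sin(w + 1) + stats::rnorm(na, 0, cfg$fluking$noise_sd)
    ay <- 0.2 * amp * sin(w + 2) + stats::rnorm(na, 0, cfg$fluking$noise_sd)
    az <- 9.81 + amp * sin(w) + stats::rnorm(na, 0, cfg$fluking$noise_sd)
    add_flinch <- function(t0, a0) {
      Tf <- cfg$startle$flinch_duration
      i <- which(ta >= t0 & ta < t0 + Tf)
      if (length(i) == 0) return()
      bump <- a0 / sqrt(3) * sin(pi * (ta[i] - t0) / Tf)
      ax[i] <<- ax[i] + bump; ay[i] <<- ay[i] + bump; az[i] <<- az[i] + bump
    }
    for (t0 in startle_times) add_flinch(t0, cfg$startle$amplitude)
    for (b in buzz_df$start) add_flinch(b, cl$buzz_jerk)
    accel <- list(data = unname(cbind(ax, ay, az)), fs = cfg$accel_fs)
  }

  ## --- ECG ----------------------------------------------------------------
  ecg <- NULL
  r_times <- numeric(0)
  if ("ecg" %in% cfg$streams) {
    sch <- cfg$fh$schedule
    tgrid <- seq(0, dur, by = 0.005)
    bpm <- if (nrow(sch) == 1) rep(sch$bpm, length(tgrid)) else
      stats::approx(sch$time, sch$bpm, xout = tgrid, rule = 2)$y
    beats_cum <- cumsum(bpm / 60 * 0.005)
    n_beats <- floor(max(beats_cum))
    r_times <- stats::approx(beats_cum, tgrid, xout = seq_len(n_beats))$y
    r_times <- r_times[!is.na(r_times)]
    fs_e <- cfg$fh$ecg_fs
    ne <- floor(dur * fs_e)
    sig <- stats::rnorm(ne, 0, cfg$fh$noise_sd)
    gauss <- function(tt, mu, sd, a) a * exp(-(tt - mu)^2 / (2 * sd^2))
    span <- seq(-0.25, 0.3, by = 1 / fs_e)
    template <- gauss(span, 0, 0.008, 1) + gauss(span, -0.025, 0.006, -0.15) +
      gauss(span, 0.025, 0.006, -0.12) + gauss(span, -0.16, 0.025, 0.12) +
      gauss(span, 0.18, 0.04, 0.2)
    for (rt in r_times) {
      i0 <- round((rt - 0.25) * fs_e) + 1
      idx <- i0:(i0 + length(template) - 1)
      ok <- idx >= 1 & idx <= ne
      sig[idx[ok]] <- sig[idx[ok]] + template[ok]
    }
    ecg <- list(data = sig, fs = fs_e)
  }

  ## --- GPS fixes ----------------------------------------------------------
  gps <- NULL
  if ("gps" %in% cfg$streams) {
    fi <- cfg$gps$fix_interval
    ft <- cumsum(stats::runif(ceiling(dur / fi[1]) + 1, fi[1], fi[2]))
    ft <- ft[ft < dur]
    if (length(ft) >= 1) {
      fx <- stats::approx(tg, x, xout = ft)$y + stats::rnorm(length(ft), 0, cfg$gps$sigma)
      fy <- stats::approx(tg, y, xout = ft)$y + stats::rnorm(length(ft), 0, cfg$gps$sigma)
      fll <- enu_to_latlon(fx, fy, cfg$position$ahd_lat, cfg$position$ahd_lon)
      gps <- gps_fixes(ft, fll$lat, fll$lon)
    }
  }

  ## --- audio --------------------------------------------------------------
  audio <- NULL
  sel_true <- rep(NA_real_, length(emit))
  if ("audio" %in% cfg$streams) {
    fs <- cfg$audio_fs
    n <- floor(dur * fs)
    p <- stats::rnorm(n, 0, db_to_pa(cfg$noise$level_db))
    add_seg <- function(t0, seg) {
      i0 <- round(t0 * fs) + 1
      idx <- i0:(i0 + length(seg) - 1)
      ok <- idx >= 1 & idx <= n
      p[idx[ok]] <<- p[idx[ok]] + seg[ok]
    }
    # AHD pings
    hl <- 10^(cfg$ahd$harmonic_levels / 20)
    tt <- seq(0, cfg$ahd$ping_duration - 1 / fs, by = 1 / fs)
    ramp_n <- round(cfg$ahd$ramp * fs)
    env <- rep(1, length(tt))
    if (ramp_n > 1) {
      up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      env[seq_len(ramp_n)] <- up
      env[(length(tt) - ramp_n + 1):length(tt)] <- rev(up)
    }
    carrier <- sin(2 * pi * cfg$ahd$base_freq * tt)
    for (h in seq_along(cfg$ahd$harmonics)) {
      if (cfg$ahd$harmonics[h] < fs / 2)
        carrier <- carrier + hl[h] * sin(2 * pi * cfg$ahd$harmonics[h] * tt)
    }
    hl_in <- hl[cfg$ahd$harmonics < fs / 2]
    amp_unit <- sqrt(2 / (1 + sum(hl_in^2)))
    for (i in seq_along(emit)) {
      seg <- db_to_pa(rl_true[i]) * amp_unit * carrier * env
      if (cfg$ahd$reverb) {
        tau <- cfg$ahd$reverb_tau
        tail_n <- round(3 * tau * fs)
        h_rev <- c(1, 0.2 * stats::rnorm(tail_n) *
                     exp(-seq_len(tail_n) / (tau * fs)))
        seg <- stats::convolve(seg, rev(h_rev), type = "open")
      }
      sel_true[i] <- 10 * log10(sum(seg^2) / fs) + 120
      add_seg(arrival[i], seg)
    }
    # clicks: Gaussian-enveloped tone pips scaled to an exact peak-to-peak
    if (nrow(click_df) > 0) {
      if (fs < 2 * cl$center_freq)
        stop("audio_fs too low to synthesize ", cl$center_freq, " Hz clicks; ",
             "lower clicks$rate_cpm to 0 or raise audio_fs")
      ct <- seq(-4 * cl$sigma, 4 * cl$sigma, by = 1 / fs)
      pip <- exp(-ct^2 / (2 * cl$sigma^2)) * cos(2 * pi * cl$center_freq * ct)
      pip_pp <- max(pip) - min(pip)
      for (i in seq_len(nrow(click_df))) {
        add_seg(click_df$time[i],
                pip * db_to_pa(click_df$level_pp[i]) / pip_pp)
      }
    }
    # respiration blows: band-limited (0.1-5 kHz) quasi-noise transients
    if (length(resp_times) > 0) {
      nb <- round(cfg$respiration$blow_duration * fs)
      bt <- (seq_len(nb) - 1) / fs
      freqs <- stats::runif(30, 150, 3500)
      phases <- stats::runif(30, 0, 2 * pi)
      blow <- rowSums(sapply(seq_along(freqs),
                             function(i) sin(2 * pi * freqs[i] * bt + phases[i])))
      blow <- blow * sin(pi * bt / cfg$respiration$blow_duration)  # fade
      blow <- blow / rms(blow) * db_to_pa(cfg$respiration$level_db)
      for (t0 in resp_times) add_seg(t0, blow)
    }
    audio <- list(data = p, fs = fs, clip_db = cfg$clip_db)
  }

  deployment <- sensor_deployment(
    deployment_id = sprintf("synthetic_seed%d", cfg$seed),
    audio = audio, accel = accel, depth = depth, ecg = ecg, gps = gps,
    exposure = exposure_meta(es, ee, cfg$position$ahd_lat,
                             cfg$position$ahd_lon, cfg$ahd$source_level,
                             cfg$ahd$ping_duration))
  truth <- structure(list(
    pings = data.frame(emit = emit, time = arrival, range = r_emit,
                       rl = rl_true, sel = sel_true),
    clicks = click_df, buzzes = buzz_df, social_runs = social_df,
    startle_times = startle_times, respiration_times = resp_times,
    r_times = r_times, track = track, crypsis = crypsis_true,
    seafloor_depth = sf_depth, config = cfg), class = "ground_truth")
  list(deployment = deployment, truth = truth)
}

#' Generate a flight-response scenario
#'
#' Convenience wrapper around [generate_deployment()]: the animal travels at
#' `pre_speed` before the exposure and switches to `exp_speed` (heading away
#' from the source) at exposure start; fluking amplitude scales with speed so
#' swimming effort increases, and received ping levels decay as the range
#' opens.
#'
#' @param config a [scenario_config()].
#' @param pre_speed,exp_speed horizontal speeds, m/s (> 0).
#' @return as [generate_deployment()].
#' @export
generate_flight_scenario <- function(config, pre_speed, exp_speed) {
  if (pre_speed <= 0 || exp_speed <= 0) stop("speeds must be > 0")
  config$track$speed <- c(pre_speed, exp_speed)
  config$track$heading <- 180
  config$fluking$amp <- NULL
  generate_deployment(config)
}
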