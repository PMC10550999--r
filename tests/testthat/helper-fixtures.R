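# Shared synthetic fixtures, built once per test run. Raw audio is dropped
# after the detectors have run so the suite keeps a small footprint.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# ping dosimetry scenario: stationary-ish animal, 29 pings, high SNR
fx_ping <- function() fixture("ping", function() {
  cfg <- scenario_config(
    seed = 7, duration = 120, exposure_start = 30, exposure_end = 120,
    audio_fs = 120000, ahd = list(interval_range = c(0.6, 6)),
    position = list(start_range = 1000),
    track = list(speed = 1.5, heading = 180),
    clicks = list(rate_cpm = 0), streams = c("audio", "accel", "depth"))
  g <- generate_deployment(cfg)
  pings <- ping_detections(g$deployment$audio)
  list(truth = g$truth, pings = pings,
       clip_db = g$deployment$audio$clip_db)
})

# fleeing animal with GPS: RL decays as the range opens
fx_flee <- function() fixture("flee", function() {
  cfg <- scenario_config(
    seed = 2, duration = 420, exposure_start = 30, exposure_end = 420,
    audio_fs = 120000, ahd = list(interval_range = c(4, 12)),
    position = list(start_range = 800), clicks = list(rate_cpm = 0),
    gps = list(fix_interval = c(30, 60)),
    streams = c("audio", "gps", "accel", "depth"))
  g <- generate_flight_scenario(cfg, 1.5, 1.8)
  pings <- ping_detections(g$deployment$audio)
  list(truth = g$truth, pings = pings, gps = g$deployment$gps,
       source = c(lat = cfg$position$ahd_lat, lon = cfg$position$ahd_lon))
})

# click and buzz scenario with two programmed buzzes and two social runs
fx_clicks <- function() fixture("clicks", function() {
  cfg <- scenario_config(
    seed = 5, duration = 120, exposure_start = 60, exposure_end = 120,
    audio_fs = 288000,
    clicks = list(rate_cpm = 30, buzz_rate_per_min = c(2, 2),
                  social_runs = 2),
    startle = list(enabled = FALSE),
    streams = c("audio", "accel", "depth"))
  g <- generate_deployment(cfg)
  fs <- g$deployment$audio$fs
  hp <- highpass_clicks(g$deployment$audio$data, fs)
  ct <- detect_clicks(hp, fs)
  ok <- ct > 0.011 & ct < 120 - 0.011
  lv <- vapply(ct[ok], function(t0) click_apparent_level(hp, fs, t0), 0)
  jerk <- compute_jerk(g$deployment$accel$data, g$deployment$accel$fs)
  list(truth = g$truth, click_times = ct,
       clicks = data.frame(time = ct[ok], level_pp = lv), jerk = jerk)
})

# ECG with a programmed 39-185 bpm ramp
fx_ecg <- function() fixture("ecg", function() {
  cfg <- scenario_config(
    seed = 11, duration = 300, exposure_start = 150, exposure_end = 300,
    fh = list(schedule = data.frame(time = c(0, 300), bpm = c(39, 185))),
    streams = "ecg")
  g <- generate_deployment(cfg)
  pre <- preprocess_ecg(g$deployment$ecg)
  list(truth = g$truth, r_det = detect_r_peaks(pre))
})
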