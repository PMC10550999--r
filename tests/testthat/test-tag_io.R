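test_that("WAV round trips are exact for float and quantized for PCM16", {
  x <- cbind(sin(2 * pi * 440 * (0:999) / 8000) * 0.8,
             cos(2 * pi * 220 * (0:999) / 8000) * 0.5)
  pf <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 8000, pf, format = "float")
  w <- read_wav(pf)
  expect_equal(w$fs, 8000)
  expect_equal(w$samples, x, tolerance = 1e-7)
  pq <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 8000, pq, format = "pcm16")
  wq <- read_wav(pq)
  expect_lt(max(abs(wq$samples - x)), 1 / 32768)
})

test_that("clip level maps full scale to the clip pressure on read", {
  # full-scale square wave with a 175 dB re 1 uPa clip level:
  # peak pressure 10^(175/20) uPa = 562.34 Pa
  dir <- withr::local_tempdir()
  write_wav(rep(c(1, -1), 400), 1000, file.path(dir, "audio.wav"))
  utils::write.csv(data.frame(time = (0:79) / 100, ax = 0, ay = 0, az = 9.81,
                              depth = 0.2),
                   file.path(dir, "sensors.csv"), row.names = FALSE)
  jsonlite::write_json(list(clip_level_db = 175,
                            rates = list(accel = 100, depth = 100)),
                       file.path(dir, "calib.json"), auto_unbox = TRUE)
  dep <- read_deployment(file.path(dir, "audio.wav"),
                         file.path(dir, "sensors.csv"),
                         file.path(dir, "calib.json"))
  expect_equal(max(dep$audio$data), 10^(175 / 20) / 1e6, tolerance = 1e-6)
  expect_null(dep$gps)
  expect_equal(length(dep$audio$data) / dep$audio$fs, 0.8)
})

test_that("a synthetic deployment survives a write/read round trip", {
  cfg <- scenario_config(seed = 3, duration = 10, exposure_start = 5,
                         exposure_end = 10, audio_fs = 96000,
                         ahd = list(interval_range = c(0.6, 2)),
                         clicks = list(rate_cpm = 0),
                         gps = list(fix_interval = c(2, 4)),
                         fh = list(schedule = data.frame(time = 0, bpm = 120)),
                         streams = c("audio", "accel", "depth", "ecg", "gps"))
  dep <- generate_deployment(cfg)$deployment
  dir <- withr::local_tempdir()
  write_deployment(dep, dir)
  back <- read_deployment(file.path(dir, "audio.wav"),
                          file.path(dir, "sensors.csv"),
                          file.path(dir, "calib.json"),
                          file.path(dir, "gps.csv"))
  expect_equal(back$audio$fs, dep$audio$fs)
  expect_equal(back$audio$data, dep$audio$data,
               tolerance = 2e-7 * db_to_pa(dep$audio$clip_db))
  expect_equal(back$accel$data, dep$accel$data, tolerance = 1e-9)
  expect_equal(back$depth$data, dep$depth$data, tolerance = 1e-9)
  expect_equal(back$ecg$data, dep$ecg$data, tolerance = 1e-9)
  expect_equal(back$gps$lat, dep$gps$lat, tolerance = 1e-9)
  expect_equal(back$exposure$exposure_start, dep$exposure$exposure_start)
  expect_equal(back$exposure$source_level, dep$exposure$source_level)
})

test_that("read_deployment validates inputs", {
  dir <- withr::local_tempdir()
  write_wav(numeric(1000), 1000, file.path(dir, "audio.wav"))
  utils::write.csv(data.frame(time = 0, ax = 0, ay = 0, az = 9.81),
                   file.path(dir, "sensors.csv"), row.names = FALSE)
  jsonlite::write_json(list(clip_level_db = 175,
                            rates = list(accel = 100, depth = 100)),
                       file.path(dir, "calib.json"), auto_unbox = TRUE)
  expect_error(read_deployment(file.path(dir, "audio.wav"),
                               file.path(dir, "sensors.csv"),
                               file.path(dir, "calib.json")),
               "depth")
  utils::write.csv(data.frame(time = 0, ax = 0, ay = 0, az = 9.81, depth = 1),
                   file.path(dir, "sensors.csv"), row.names = FALSE)
  jsonlite::write_json(list(clip_level_db = 175,
                            rates = list(accel = -5, depth = 100)),
                       file.path(dir, "calib.json"), auto_unbox = TRUE)
  expect_error(read_deployment(file.path(dir, "audio.wav"),
                               file.path(dir, "sensors.csv"),
                               file.path(dir, "calib.json")),
               "positive")
})

test_that("decimation preserves band-limited signals and rejects aliases", {
  t <- (0:3999) / 200
  cst <- decimate_series(rep(2.5, 4000), 200, 25)
  expect_equal(cst$fs, 25)
  expect_equal(cst$data, rep(2.5, 500), tolerance = 1e-6)
  s1 <- decimate_series(sin(2 * pi * t), 200, 25)
  mid <- 100:400
  expect_equal(max(abs(s1$data[mid])), 1, tolerance = 0.01)
  # rms preserved within 1% for a signal below 0.4 x target rate
  expect_equal(rms(s1$data[mid]), 1 / sqrt(2), tolerance = 0.01)
  s90 <- decimate_series(sin(2 * pi * 90 * t), 200, 25)
  expect_lt(max(abs(s90$data[mid])), 0.05)
  expect_error(decimate_series(sin(t), 200, 300), "below")
})

test_that("event CSVs round trip and enforce time ordering", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(data.frame(time = numeric(0), rl = numeric(0)), p)
  expect_equal(nrow(read_events(p)), 0)
  ev <- data.frame(time = c(1.5, 2.25, 9), rl = c(120, 121.5, 119),
                   accepted = c(TRUE, FALSE, TRUE))
  write_events(ev, p)
  expect_equal(read_events(p), ev)
  big <- data.frame(time = sort(runif(1e4, 0, 3600)),
                    level_pp = rnorm(1e4, 150, 3))
  write_events(big, p)
  expect_equal(read_events(p), big, tolerance = 1e-12)
  expect_error(write_events(data.frame(time = c(2, 1)), p), "ordered")
})

test_that("Pa/dB conversion is self-inverse across the tag dynamic range", {
  db <- seq(60, 175, by = 5)
  expect_equal(pa_to_db(db_to_pa(db)), db)
  expect_equal(pa_to_db(1 / sqrt(2)), 116.9897, tolerance = 1e-4)
})

test_that("deployment validation catches impossible streams", {
  aud <- list(data = c(0, 1000), fs = 1000, clip_db = 120)  # > 1 Pa clip
  expect_error(sensor_deployment("x", aud,
                                 list(data = matrix(0, 2, 3), fs = 100),
                                 list(data = c(0, 0), fs = 10)),
               "clip")
  aud$data <- c(0, 0.5)
  expect_error(sensor_deployment("x", aud,
                                 list(data = matrix(0, 2, 3), fs = 100),
                                 list(data = c(-3, 0), fs = 10)),
               "depth")
})
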