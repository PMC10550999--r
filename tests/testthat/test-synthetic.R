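test_that("fixed seed reproduces the deployment bit for bit", {
  cfg <- scenario_config(seed = 9, duration = 8, exposure_start = 4,
                         exposure_end = 8, audio_fs = 96000,
                         ahd = list(interval_range = c(0.6, 2)),
                         clicks = list(rate_cpm = 0),
                         streams = c("audio", "accel", "depth"))
  g1 <- generate_deployment(cfg)
  g2 <- generate_deployment(cfg)
  expect_identical(g1$deployment$audio$data, g2$deployment$audio$data)
  expect_identical(g1$deployment$accel$data, g2$deployment$accel$data)
  expect_identical(g1$truth$pings, g2$truth$pings)
  expect_identical(g1$truth$respiration_times, g2$truth$respiration_times)
})

test_that("true RL follows the closed-form propagation at fixed range", {
  # SL 189, spherical + 1.5 dB/km, animal pinned at 1000 m:
  # RL = 189 - 60 - 1.5 = 127.5 for every ping
  cfg <- scenario_config(seed = 4, duration = 30, exposure_start = 5,
                         exposure_end = 30,
                         ahd = list(interval_range = c(0.6, 3)),
                         position = list(start_range = 1000),
                         track = list(speed = 0), clicks = list(rate_cpm = 0),
                         streams = c("accel", "depth"))
  g <- generate_deployment(cfg)
  expect_gt(nrow(g$truth$pings), 3)
  expect_equal(g$truth$pings$rl, rep(127.5, nrow(g$truth$pings)))
})

test_that("programmed startle flinches sit exactly at ping arrival + latency", {
  cfg <- scenario_config(seed = 6, duration = 30, exposure_start = 5,
                         exposure_end = 30,
                         ahd = list(interval_range = c(0.6, 3)),
                         startle = list(enabled = TRUE, latency = 0.1,
                                        pings = 1:4),
                         clicks = list(rate_cpm = 0), streams = "accel")
  g <- generate_deployment(cfg)
  expect_equal(g$truth$startle_times, g$truth$pings$time[1:4] + 0.1)
})

test_that("ground-truth events stay inside the record", {
  for (s in 1:3) {
    cfg <- scenario_config(seed = s, duration = 40, exposure_start = 10,
                           exposure_end = 40, audio_fs = 96000,
                           ahd = list(interval_range = c(0.6, 4)),
                           clicks = list(rate_cpm = 0),
                           streams = c("audio", "accel", "depth"))
    tr <- generate_deployment(cfg)$truth
    ev <- c(tr$pings$time, tr$startle_times, tr$respiration_times)
    expect_true(all(ev >= 0 & ev <= 40))
    expect_true(!is.unsorted(tr$pings$time))
    expect_true(all(tr$pings$rl <= 189))
  }
})

test_that("config validation rejects impossible scenarios", {
  expect_error(scenario_config(duration = 10, exposure_start = 8,
                               exposure_end = 8.2,
                               ahd = list(ping_duration = 0.5)),
               "too short")
  expect_error(scenario_config(duration = 5, exposure_start = 4,
                               exposure_end = 10), "cover")
  expect_error(generate_flight_scenario(scenario_config(), -1, 2), "> 0")
})

test_that("flight scenarios recover the programmed speed change from GPS", {
  # equal speeds: estimated change stays near zero
  cfg0 <- scenario_config(seed = 21, duration = 1810, exposure_start = 900,
                          exposure_end = 1800,
                          position = list(start_range = 2000),
                          streams = "gps")
  g0 <- generate_flight_scenario(cfg0, 1.3, 1.3)
  legs <- leg_speeds(g0$deployment$gps)$legs
  ch0 <- 100 * (mean(legs$speed[legs$t0 >= 900]) /
                  mean(legs$speed[legs$t1 <= 900]) - 1)
  expect_lt(abs(ch0), 5)

  # 1.0 -> 2.0 m/s: mean recovered increase within 10% over 20 seeds
  incs <- vapply(1:20, function(s) {
    cfg <- scenario_config(seed = s, duration = 1810, exposure_start = 900,
                           exposure_end = 1800,
                           position = list(start_range = 2000),
                           streams = "gps")
    g <- generate_flight_scenario(cfg, 1.0, 2.0)
    legs <- leg_speeds(g$deployment$gps)$legs
    pre <- legs$speed[legs$t1 <= 900]
    ex <- legs$speed[legs$t0 >= 900]
    100 * (mean(ex) - mean(pre)) / mean(pre)
  }, 0)
  expect_lt(abs(mean(incs) - 100), 10)
})

test_that("a receding track gives a smoothly decreasing detected RL series", {
  fx <- fx_flee()
  acc <- fx$pings[fx$pings$accepted, ]
  expect_gt(nrow(acc), 20)
  sm <- stats::runmed(acc$rl_rms_fast, 5)
  mid <- 3:(length(sm) - 2)
  expect_true(all(diff(sm[mid]) <= 0.1))
  expect_lt(sm[length(sm) - 2], sm[3] - 3)
})
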