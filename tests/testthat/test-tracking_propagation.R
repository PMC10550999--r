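test_that("transmission loss follows spreading + absorption", {
  expect_equal(transmission_loss(1000), 61.5)
  expect_equal(round(transmission_loss(1000)), 62)
  cyl <- propagation_model("cylindrical", absorption = 0)
  expect_equal(transmission_loss(1000, cyl), 30)
  expect_error(transmission_loss(0.5), ">= 1")
  r <- c(1, 10, 100, 1000, 10000)
  expect_true(all(diff(transmission_loss(r)) > 0))
  expect_true(all(transmission_loss(r[-1]) >=
                    transmission_loss(r[-1], propagation_model("cylindrical"))))
})

test_that("received level inverts the source level through TL", {
  # absorption contributes only 0.0015 dB at the 1-m reference
  expect_equal(received_level(189, 1), 189, tolerance = 0.01)
  expect_equal(164 - round(transmission_loss(1000)), 102)
  noabs <- propagation_model(absorption = 0)
  expect_equal(received_level(158, 100, noabs), 118)
})

test_that("effect ranges match a brute-force grid scan", {
  pm <- propagation_model()
  grid <- seq(1, 20000, by = 1)
  rl <- received_level(190, grid, pm)
  oracle_190 <- grid[which.min(abs(rl - 100))]
  r190 <- solve_effect_range(190, 100, pm)
  expect_lt(abs(r190 - oracle_190), 1)
  expect_equal(r190 / 1000, 7.97, tolerance = 0.01)
  rl164 <- received_level(164, grid, pm)
  oracle_164 <- grid[which.min(abs(rl164 - 100))]
  r164 <- solve_effect_range(164, 100, pm)
  expect_lt(abs(r164 - oracle_164), 1)
  expect_equal(r164 / 1000, 1.28, tolerance = 0.01)
  # closed form without absorption
  expect_equal(solve_effect_range(190, 100, propagation_model(absorption = 0)),
               10^(90 / 20), tolerance = 1e-3)
  # solve and received_level are mutual inverses
  expect_equal(received_level(190, r190, pm), 100, tolerance = 0.01)
  # threshold out of bracket flags overflow
  over <- solve_effect_range(250, 60, propagation_model(absorption = 0))
  expect_true(is.na(over))
  expect_true(attr(over, "overflow"))
  expect_error(solve_effect_range(100, 120), "exceed")
})

test_that("impact areas scale with the square of the radius ratio", {
  expect_equal(impact_area_ratio(900, 300), 9)
  expect_equal(impact_area_ratio(5, 5), 1)
  expect_equal(impact_area_ratio(2200, 600), 13.44, tolerance = 0.01)
  expect_equal(impact_area_ratio(900, 300) * impact_area_ratio(300, 900), 1)
  expect_error(impact_area_ratio(-1, 5), "> 0")
})

test_that("the predicted response threshold is hearing + sensation level", {
  expect_equal(response_threshold(), 95)
  expect_equal(response_threshold(50, 45), 95)
})

test_that("geodesic ranges behave like meridian arcs", {
  expect_equal(range_to_source(55, 10, 55, 10), 0)
  expect_equal(range_to_source(45.009, 10, 45, 10), 1000, tolerance = 2)
  expect_equal(range_to_source(55.01, 10.02, 55, 10),
               range_to_source(55, 10, 55.01, 10.02))
})

test_that("leg speeds exclude unrealistic fixes and recompute across gaps", {
  # two fixes 300 m apart in 200 s -> 1.5 m/s
  f2 <- gps_fixes(c(0, 200), c(45, 45 + 300 / 111132), c(10, 10))
  tr2 <- leg_speeds(f2)
  expect_equal(tr2$legs$speed, 1.5, tolerance = 0.01)
  # an injected bad fix producing > 5 m/s is excluded
  f3 <- gps_fixes(c(0, 200, 400),
                  c(45, 45 + 1200 / 111132, 45 + 600 / 111132),
                  c(10, 10, 10))
  tr3 <- leg_speeds(f3)
  expect_true(tr3$fixes$excluded[2])
  expect_equal(nrow(tr3$legs), 1)
  expect_true(all(tr3$legs$speed <= 5))
  expect_error(leg_speeds(gps_fixes(c(0, 0), c(45, 45), c(10, 10))),
               "duplicate")
})

test_that("a straight synthetic track recovers its programmed speed", {
  cfg <- scenario_config(seed = 31, duration = 3600, exposure_start = 1800,
                         exposure_end = 3600,
                         position = list(start_range = 3000),
                         track = list(speed = 1.8, heading = 180),
                         gps = list(fix_interval = c(230, 250)),
                         streams = "gps")
  g <- generate_deployment(cfg)
  tr <- leg_speeds(g$deployment$gps)
  expect_equal(mean(tr$legs$speed), 1.8, tolerance = 0.1)
  expect_true(all(!tr$fixes$excluded))
  sm <- tr$smoothed
  expect_equal(mean(sm, na.rm = TRUE), 1.8, tolerance = 0.1)
})

test_that("Theil-Sen slope resists outliers", {
  x <- 1:20
  y <- 2 * x + 1
  y[7] <- 500
  expect_equal(theil_sen_slope(x, y), 2, tolerance = 0.01)
  expect_error(theil_sen_slope(1, 2), "2 points")
})

test_that("the RL-vs-range profile tracks the propagation model", {
  # constant-RL pings give a flat profile
  pings <- data.frame(time = seq(10, 100, by = 10), rl_rms_fast = 120,
                      sel_single = 117, snr = 30, accepted = TRUE)
  fx <- gps_fixes(c(20, 50, 80), c(55.001, 55.002, 55.003), rep(10, 3))
  prof <- rl_vs_range_profile(pings, fx, 55, 10)
  expect_equal(prof$rl_median, rep(120, 3))
  expect_false(any(prof$flagged))
  # fewer than 5 accepted pings flags the profile
  prof2 <- rl_vs_range_profile(pings[1:3, ], fx, 55, 10)
  expect_true(all(prof2$flagged))
  # on the fleeing scenario the profile decreases with range and fits the
  # spherical + absorption model within 1.5 dB rms
  flee <- fx_flee()
  prof3 <- rl_vs_range_profile(flee$pings, flee$gps,
                               flee$source["lat"], flee$source["lon"])
  o <- order(prof3$range)
  expect_true(all(diff(prof3$rl_median[o]) <= 0.5))
  resid <- prof3$rl_median -
    received_level(189, prof3$range, propagation_model())
  expect_lt(sqrt(mean(resid^2)), 1.5)
})
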