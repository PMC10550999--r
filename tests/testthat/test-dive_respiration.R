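trapezoid_depth <- function(fs = 5, cycle = c(surface = 20, down = 10,
                                              bottom = 60, up = 10),
                            max_depth = 30) {
  one <- c(rep(0.2, cycle[1] * fs),
           seq(0.2, max_depth, length.out = cycle[2] * fs),
           rep(max_depth, cycle[3] * fs),
           seq(max_depth, 0.2, length.out = cycle[4] * fs))
  list(data = rep(one, 3), fs = fs)
}

test_that("dive segmentation classifies U, V and surface records", {
  d <- trapezoid_depth()
  dv <- segment_dives(d)
  expect_equal(nrow(dv), 3)
  expect_equal(dv$max_depth, rep(30, 3))
  expect_true(all(dv$shape == "U"))
  spike <- list(data = c(rep(0.2, 50), seq(0.2, 30, length.out = 100),
                         seq(30, 0.2, length.out = 100), rep(0.2, 50)),
                fs = 5)
  expect_equal(segment_dives(spike)$shape, "V")
  flat <- list(data = rep(0.3, 500), fs = 5)
  expect_equal(nrow(segment_dives(flat)), 0)
  # partition property: dives are disjoint, ordered, and cover submerged time
  expect_true(all(diff(as.vector(rbind(dv$start, dv$end))) >= 0))
  submerged <- sum(d$data > 0.5) / d$fs
  expect_lt(abs(sum(dv$end - dv$start) - submerged), 3 * 2 / d$fs)
})

test_that("apparent seafloor interpolates U-dive depths or uses bathymetry", {
  dv <- data.frame(start = c(0, 600, 1200) - 30, end = c(0, 600, 1200) + 30,
                   max_depth = c(28, 30, 32),
                   bottom_frac = 0.8, shape = "U")
  sf <- estimate_seafloor(dv)
  expect_true(attr(sf, "available"))
  expect_equal(sf(300), 29)
  # bathymetry + GPS wins over dives
  gps <- gps_fixes(c(0, 600), c(55.0, 55.01), c(10.0, 10.0))
  grid <- expand.grid(lat = seq(54.99, 55.02, by = 0.01), lon = 10.0)
  grid$depth <- 25
  sf2 <- estimate_seafloor(dv, gps, grid)
  expect_equal(sf2(c(0, 300, 600)), rep(25, 3))
  # no U dives and no grid: unavailable
  sf3 <- estimate_seafloor(dv[0, ])
  expect_false(attr(sf3, "available"))
  expect_true(is.na(sf3(10)))
})

test_that("crypsis needs 2 m of the surface or the apparent seafloor", {
  d <- list(data = c(1.5, 28.5, 10), fs = 1)
  m <- crypsis_mask(d, seafloor = 30)
  expect_identical(m$mask, c(TRUE, TRUE, FALSE))
  expect_equal(crypsis_fraction(m, c(0, 3)), 2 / 3)
  # without a seafloor only the surface band counts
  m2 <- crypsis_mask(d, seafloor = NULL)
  expect_identical(m2$mask, c(TRUE, FALSE, FALSE))
  # deepening the seafloor never increases crypsis
  dd <- trapezoid_depth()
  c30 <- sum(crypsis_mask(dd, 30)$mask)
  c35 <- sum(crypsis_mask(dd, 35)$mask)
  expect_lte(c35, c30)
  fr <- crypsis_fraction(crypsis_mask(dd, 30), c(0, 300))
  expect_gte(fr, 0)
  expect_lte(fr, 1)
})

test_that("respiration detection recovers programmed blows at the surface", {
  cfg <- scenario_config(seed = 14, duration = 120, exposure_start = 60,
                         exposure_end = 120, audio_fs = 24000,
                         ahd = list(interval_range = c(2, 8)),
                         clicks = list(rate_cpm = 0),
                         respiration = list(rate = c(4, 3)),
                         streams = c("audio", "accel", "depth"))
  g <- generate_deployment(cfg)
  resp <- detect_respirations(g$deployment$audio, g$deployment$depth)
  tr <- g$truth$respiration_times
  expect_equal(nrow(resp), length(tr))
  expect_lt(max(vapply(tr, function(t) min(abs(resp$time - t)), 0)), 0.2)
  # every event lies at the surface
  di <- round(resp$time * g$deployment$depth$fs) + 1
  expect_true(all(g$deployment$depth$data[di] <= 1))
})

test_that("blow-like transients at depth are rejected by the depth gate", {
  fs <- 24000
  set.seed(4)
  x <- rnorm(20 * fs, 0, db_to_pa(85))
  t <- (0:(0.3 * fs - 1)) / fs
  blow <- sin(2 * pi * 800 * t) * sin(pi * t / 0.3) * db_to_pa(103)
  x[10 * fs + seq_along(blow)] <- x[10 * fs + seq_along(blow)] + blow
  deep <- list(data = rep(10, 20 * 50), fs = 50)
  expect_equal(nrow(detect_respirations(list(data = x, fs = fs), deep)), 0)
  shallow <- list(data = rep(0.3, 20 * 50), fs = 50)
  expect_equal(nrow(detect_respirations(list(data = x, fs = fs), shallow)), 1)
})

test_that("respiration rates and IRIs follow the counts", {
  t48 <- seq(0, 899, length.out = 48)
  expect_equal(respiration_rate(t48, c(0, 900)), 3.2)
  t63 <- seq(0.1, 899, length.out = 63)
  expect_equal(respiration_rate(t63, c(0, 900)), 4.2)
  expect_equal(respiration_rate(numeric(0), c(0, 900)), 0)
  even <- seq(20, 880, by = 20)
  ev <- data.frame(time = even, iri_prev = c(NA, diff(even)))
  expect_true(all(ev$iri_prev[-1] == 20))
  expect_equal(respiration_rate(even, c(10, 890)), 3, tolerance = 0.01)
})
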