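tone <- function(freq, fs, dur, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs)
}
mid_rms <- function(x) rms(x[round(length(x) * 0.25):round(length(x) * 0.75)])

test_that("the 10-46 kHz band-pass keeps the ping and rejects its neighbours", {
  fs <- 400000
  in_band <- bandpass_ahd(tone(14000, fs, 0.2), fs)
  expect_lt(abs(pa_to_db(mid_rms(in_band)) - pa_to_db(1 / sqrt(2))), 1)
  low <- bandpass_ahd(tone(5000, fs, 0.2), fs)
  expect_gt(pa_to_db(1 / sqrt(2)) - pa_to_db(mid_rms(low)), 30)
  hi <- bandpass_ahd(tone(130000, fs, 0.2), fs)
  expect_gt(pa_to_db(1 / sqrt(2)) - pa_to_db(mid_rms(hi)), 40)
  expect_error(bandpass_ahd(tone(14000, 90000, 0.1), 90000), "too low")
})

test_that("ping detection finds close pairs and nothing in silence", {
  fs <- 120000
  expect_length(detect_pings(numeric(fs), fs), 0)
  # two pings at the minimum 0.6-s spacing resolve separately
  x <- rnorm(3 * fs, 0, 1e-4)
  p <- tone(14000, fs, 0.5, 0.1)
  for (t0 in c(1.0, 1.6)) {
    i <- round(t0 * fs) + seq_along(p)
    x[i] <- x[i] + p
  }
  det <- detect_pings(x, fs)
  expect_length(det, 2)
  expect_equal(det, c(1.0, 1.6), tolerance = 0.005)
})

test_that("rms-fast RL matches the closed form for a calibrated tone", {
  fs <- 100000
  x <- c(numeric(fs / 10), tone(14000, fs, 0.3), numeric(fs / 10))
  # 1 Pa amplitude: rms 1/sqrt(2) Pa -> 116.99 dB re 1 uPa
  expect_equal(measure_rl_rms_fast(x, fs, 0.1), 116.9897, tolerance = 0.01)
  expect_equal(measure_rl_rms_fast(x, fs, 0.1, anchor = "onset"), 116.9897,
               tolerance = 0.01)
  expect_error(measure_rl_rms_fast(x[1:1000], fs, 0.1), "beyond")
})

test_that("SNR separates pings from the noise floor with a strict 10-dB gate", {
  fs <- 100000
  set.seed(1)
  noise <- rnorm(fs, 0, 0.01)
  x <- noise
  i <- round(0.4 * fs) + seq_len(0.5 * fs)
  x[i] <- x[i] + tone(14000, fs, 0.5, 0.01 * sqrt(2) * 10)  # ~ +20 dB
  expect_equal(measure_snr(x, fs, 0.4), 20, tolerance = 1.5)
  # no ping: measured "ping" rms equals noise rms, SNR ~ 0 -> rejected
  expect_lt(measure_snr(noise, fs, 0.4), 3)
  fx <- fx_ping()
  expect_identical(fx$pings$accepted, fx$pings$snr > 10)
})

test_that("single-ping SEL follows the rms + duration closed form", {
  fs <- 100000
  x <- c(numeric(fs / 10), tone(14000, fs, 0.5), numeric(fs / 10))
  # 500-ms tone at 116.99 dB rms: SEL = 116.99 + 10 log10(0.5) = 113.98
  expect_equal(ping_sel(x, fs, 0.1), 113.9794, tolerance = 0.02)
  expect_error(ping_sel(x, fs, 0.5), "beyond")
  # rectangular ping: sel = rl + 10 log10(d) within 0.2 dB
  fx <- fx_ping()
  expect_true(all(abs(fx$pings$sel_single - fx$pings$rl_rms_fast -
                        10 * log10(0.5)) < 0.2))
})

test_that("a reverberant ping carries at least the clean ping's energy", {
  base <- list(seed = 13, duration = 6, exposure_start = 2, exposure_end = 6,
               audio_fs = 96000, ahd = list(interval_range = c(3, 3.5)),
               clicks = list(rate_cpm = 0),
               streams = c("audio", "accel", "depth"))
  clean <- generate_deployment(do.call(scenario_config, base))
  base$ahd$reverb <- TRUE
  rev <- generate_deployment(do.call(scenario_config, base))
  expect_true(all(rev$truth$pings$sel >= clean$truth$pings$sel))
})

test_that("SELcum is a non-leaky, order-insensitive, monotone energy sum", {
  p10 <- data.frame(time = 1:10, rl_rms_fast = 117, sel_single = 113.9794,
                    snr = 30, accepted = TRUE)
  d <- cumulate_sel(p10)
  expect_equal(max(d$selcum), 113.9794 + 10, tolerance = 1e-9)
  expect_true(all(diff(d$selcum) > 0))
  # single ping at the TTS threshold trips the exceedance flag at margin 0
  one <- data.frame(time = 1, rl_rms_fast = 145, sel_single = 142, snr = 30,
                    accepted = TRUE)
  expect_true(cumulate_sel(one, margin = 0)$tts_exceeded)
  expect_false(cumulate_sel(data.frame(time = 1, rl_rms_fast = 120,
                                       sel_single = 117, snr = 30,
                                       accepted = TRUE))$tts_risk)
  # permutation of SEL values leaves the final dose unchanged
  set.seed(2)
  sel <- runif(12, 100, 130)
  a <- data.frame(time = 1:12, rl_rms_fast = sel + 3, sel_single = sel,
                  snr = 30, accepted = TRUE)
  b <- a
  b$sel_single <- sample(sel)
  expect_equal(max(cumulate_sel(a)$selcum), max(cumulate_sel(b)$selcum))
  expect_error(cumulate_sel(a[c(2, 1, 3:12), ]), "ordered")
})

test_that("detected pings recover the ground-truth dose within 1 dB", {
  fx <- fx_ping()
  tr <- fx$truth$pings
  p <- fx$pings
  expect_equal(nrow(p), nrow(tr))
  i <- vapply(tr$time, function(t) which.min(abs(p$time - t)), 1L)
  expect_lt(max(abs(p$time[i] - tr$time)), 0.005)
  acc <- p$accepted[i]
  expect_true(all(abs(p$rl_rms_fast[i][acc] - tr$rl[acc]) <= 1))
  expect_true(all(p$rl_rms_fast <= fx$clip_db))
  expect_true(all(p$sel_single <= p$rl_rms_fast + 2))  # loose sanity bound
})
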