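# A six-animal synthetic exposure battery.
#
# Six scenarios programmed with the direction pattern observed across the
# six tagged porpoises: which animals startled, fled, suppressed or raised
# their click rate and output level, changed swimming effort and
# respiration rate, went more or less cryptic, and which accumulated a dose
# close to the TTS reference. Animal 6 carries a mid-frequency (240 kHz)
# tag on which NBHF clicks cannot be measured, so its click cells are
# undefined. Used by the end-to-end recovery tests: the pipeline must
# reproduce every programmed flag and sign.

#' Build the six-scenario synthetic exposure battery
#'
#' Each scenario approaches the source before the exposure and (except the
#' non-fleeing animal 4) turns away at exposure start. `exposure_range` per
#' scenario is the animal-source range at exposure start; the three closest
#' exposures accumulate doses near or above the TTS reference, the far ones
#' do not. Respiration rates are chosen so that the programmed direction
#' survives breath-count quantization at the configured window length.
#'
#' @param window pre-exposure / exposure window length, s (15 min in the
#'   full design; shorter windows scale the problem down for testing, with
#'   ping intervals capped at `window / 10`).
#' @param audio_fs audio rate for the five high-frequency tags, Hz.
#' @param seed base seed; scenario i uses `seed + i`.
#' @return list with `configs` (six [scenario_config()] objects) and
#'   `expected` (data.frame of programmed flags and signs: startle,
#'   crypsis_sign, click_rate_sign, click_level_sign, msa_sign, fled,
#'   resp_sign, tts_risk).
#' @export
scenario_battery <- function(window = 900, audio_fs = 500000, seed = 1) {
  pars <- data.frame(
    id = paste0("A", 1:6),
    startle = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    cry_pre = c(0.72, 0.59, 0.80, 0.60, 0.64, 0.63),
    cry_diff = c(-2, 33, 8, 10, 15, 26) / 100,
    cpm_pre = c(120, 20, 120, 120, 120, 0),
    cpm_chg = c(-39, 690, -98, -27, -53, NA),
    lvl_chg = c(-8, -1, -1, -2, -8, NA),
    amp_pre = c(1.2, 1.2, 1.2, 1.6, 1.2, 1.2),
    msa_chg = c(17, 25, 32, -31, 75, 141),
    fled = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    speed_pre = c(1.3, 1.3, 1.4, 0.5, 1.3, 1.4),
    speed_exp = c(1.4, 1.6, 1.8, 0.5, 1.9, 2.0),
    resp_pre = c(3.7, 3.4, 3.2, 3.9, 3.4, 3.9),
    resp_chg = c(-11, 5, 31, -15, 4, -13),
    exposure_range = c(550, 550, 600, 4500, 7000, 3000),
    tts_risk = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    gps = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))

  configs <- lapply(1:6, function(i) {
    p <- pars[i, ]
    fled_i <- p$fled
    scenario_config(
      seed = seed + i,
      duration = 2 * window + 10,
      exposure_start = window, exposure_end = 2 * window,
      audio_fs = if (i == 6) 240000 else audio_fs,
      ahd = list(interval_range = c(0.6, min(90, window / 10))),
      position = list(
        start_range = p$exposure_range +
          (if (fled_i) p$speed_pre * window else 0)),
      track = list(
        speed = c(p$speed_pre, p$speed_exp),
        heading = if (fled_i) c(0, 180) else 90),
      dive = list(crypsis_frac = c(p$cry_pre, p$cry_pre + p$cry_diff)),
      clicks = if (p$cpm_pre > 0) list(
        rate_cpm = c(p$cpm_pre, p$cpm_pre * (1 + p$cpm_chg / 100)),
        level_pp = c(150, 150 + p$lvl_chg)) else list(rate_cpm = 0),
      startle = list(enabled = p$startle),
      fluking = list(amp = c(p$amp_pre, p$amp_pre * (1 + p$msa_chg / 100))),
      respiration = list(rate = c(p$resp_pre,
                                  p$resp_pre * (1 + p$resp_chg / 100))),
      streams = c("audio", "accel", "depth", if (p$gps) "gps"))
  })

  expected <- data.frame(
    id = pars$id,
    startle = pars$startle,
    crypsis_sign = sign(pars$cry_diff),
    click_rate_sign = sign(pars$cpm_chg),
    click_level_sign = sign(pars$lvl_chg),
    msa_sign = sign(pars$msa_chg),
    fled = pars$fled,
    resp_sign = sign(pars$resp_chg),
    tts_risk = pars$tts_risk)
  list(configs = configs, expected = expected)
}

#' Ground-truth response directions for a battery scenario
#'
#' Computes, from a scenario's ground-truth event log, the direction each
#' event-driven response cell should take over a window pair: crypsis
#' fraction difference, click-rate change, click-level (95th percentile)
#' change, and respiration-rate change. Cells whose truth is undefined in a
#' window (e.g. no clicks during the exposure after a near-total click-rate
#' suppression, or a tag that records no clicks at all) come back `NA`, and
#' the pipeline is expected to report the matching cell as undefined.
#'
#' @param truth a `ground_truth` object from [generate_deployment()].
#' @param windows a [window_pair()].
#' @return one-row data.frame: crypsis, click_rate, click_level, resp
#'   (each -1, 0, 1 or NA).
#' @export
battery_truth_signs <- function(truth, windows) {
  wp <- windows
  cl <- truth$clicks
  if (is.null(cl) || nrow(cl) == 0) {
    cr <- NA_real_
    lv <- NA_real_
  } else {
    cr <- sign(click_rate(cl$time, wp$exposure) -
                 click_rate(cl$time, wp$pre))
    lp <- level_percentile(cl, wp$pre)
    le <- level_percentile(cl, wp$exposure)
    lv <- if (is.na(lp) || is.na(le)) NA_real_ else
      sign(as.numeric(le) - as.numeric(lp))
  }
  resp <- sign(respiration_rate(truth$respiration_times, wp$exposure) -
                 respiration_rate(truth$respiration_times, wp$pre))
  tc <- truth$crypsis
  mask <- list(mask = tc$mask, fs = tc$fs,
               times = (seq_along(tc$mask) - 1) / tc$fs)
  cry <- sign(crypsis_fraction(mask, wp$exposure) -
                crypsis_fraction(mask, wp$pre))
  data.frame(crypsis = cry, click_rate = cr, click_level = lv, resp = resp)
}
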