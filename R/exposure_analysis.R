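# Pre-exposure vs exposure comparison and the per-animal response table.
#
# Acute exposure effects are measured by comparing the exposure interval
# with a control interval of the same length immediately preceding it (15
# min each when the record allows). Percent changes are reported rounded to
# the nearest integer (half away from zero); click output levels are
# differenced in dB, never percent-changed. The response index counts, per
# animal, the criteria showing a response irrespective of direction.

#' Pre-exposure / exposure window pair
#'
#' The control window immediately precedes the exposure and has the same
#' length; both are capped at `max_len` (15 min) and shrink together when
#' the exposure or the available pre-roll is shorter.
#'
#' @param exposure an [exposure_meta()] (or numeric start).
#' @param exposure_end exposure end if `exposure` is numeric.
#' @param max_len cap, s.
#' @param record_start earliest usable time, s.
#' @return list of class `window_pair` with `pre` and `exposure` intervals.
#' @export
window_pair <- function(exposure, exposure_end = NULL, max_len = 900,
                        record_start = 0) {
  if (inherits(exposure, "exposure_meta")) {
    es <- exposure$exposure_start
    ee <- exposure$exposure_end
  } else {
    es <- exposure
    ee <- exposure_end
  }
  len <- min(max_len, ee - es, es - record_start)
  if (len <= 0) stop("no usable pre-exposure interval before the exposure")
  structure(list(pre = c(es - len, es), exposure = c(es, es + len)),
            class = "window_pair")
}

#' Percent change from a pre to a post value
#'
#' `100 (post - pre) / pre`, rounded half away from zero to the nearest
#' integer (the reporting precision of the response table). `NA` with
#' attribute `defined = FALSE` when `pre` is 0 or either value is missing.
#'
#' @param pre,post values on a ratio scale.
#' @return percent change (integer-valued numeric), or flagged `NA`.
#' @export
percent_change <- function(pre, post) {
  if (is.na(pre) || is.na(post) || pre == 0)
    return(structure(NA_real_, defined = FALSE))
  structure(round_half_away(100 * (post - pre) / pre), defined = TRUE)
}

#' dB change from a pre to a post level
#'
#' Levels are differenced (never percent-changed); rounded to one decimal.
#'
#' @param pre_db,post_db levels in dB.
#' @return change in dB, or flagged `NA` when either side is undefined.
#' @export
db_change <- function(pre_db, post_db) {
  if (is.na(pre_db) || is.na(post_db))
    return(structure(NA_real_, defined = FALSE))
  structure(round_half_away(post_db - pre_db, 1), defined = TRUE)
}

#' Flight (increased distance to source) flag
#'
#' Fled is TRUE when the robust (Theil-Sen) trend of accepted ping RLs over
#' the exposure is below `slope_db_min` dB/min (the animal opening range
#' shows as decaying RL), or when the GPS range to the source trends
#' upward. Both indicators are reported; the flag is their OR over the
#' defined ones, and `NA` when neither is evaluable (fewer than `min_pings`
#' accepted pings and no usable track).
#'
#' @param pings ping table ([ping_detections()]).
#' @param window exposure interval, length-2 numeric.
#' @param track optional [leg_speeds()] result or [gps_fixes()].
#' @param source_lat,source_lon AHD position (needed with `track`).
#' @param slope_db_min RL trend threshold, dB per minute.
#' @param min_pings minimum accepted pings for the RL trend.
#' @return logical flag with attributes `rl_slope_db_min` and
#'   `gps_range_slope` (m/s).
#' @export
flight_flag <- function(pings, window, track = NULL, source_lat = NULL,
                        source_lon = NULL, slope_db_min = -0.2,
                        min_pings = 10) {
  acc <- pings[pings$accepted & pings$time >= window[1] &
                 pings$time <= window[2], , drop = FALSE]
  rl_slope <- NA_real_
  fled_rl <- NA
  if (nrow(acc) >= min_pings) {
    rl_slope <- theil_sen_slope(acc$time / 60, acc$rl_rms_fast)
    fled_rl <- rl_slope < slope_db_min
  }
  gps_slope <- NA_real_
  fled_gps <- NA
  if (!is.null(track) && !is.null(source_lat)) {
    fixes <- if (inherits(track, "track_estimate")) {
      track$fixes[!track$fixes$excluded, ]
    } else as.data.frame(track)
    fixes <- fixes[fixes$time >= window[1] & fixes$time <= window[2], ]
    if (nrow(fixes) >= 2) {
      rngs <- range_to_source(fixes$lat, fixes$lon, source_lat, source_lon)
      gps_slope <- theil_sen_slope(fixes$time, rngs)
      fled_gps <- gps_slope > 0
    }
  }
  fled <- if (is.na(fled_rl) && is.na(fled_gps)) NA else
    isTRUE(fled_rl) || isTRUE(fled_gps)
  structure(fled, rl_slope_db_min = rl_slope, gps_range_slope = gps_slope)
}

#' Response index from a row of response-table cells
#'
#' Counts the criteria showing a response irrespective of direction: the
#' boolean criteria (startle, fled, TTS risk) count when TRUE; percent /
#' percentage-point cells count when their magnitude reaches `threshold`;
#' the click-level cell counts when its magnitude reaches `threshold` dB.
#' Undefined (NA) cells never count. The magnitude rule is a reconstruction
#' (it is the simple threshold consistent with the published per-animal
#' indices) and is exposed as a parameter.
#'
#' @param cells list or one-row data.frame with startle, crypsis_diff,
#'   click_rate_change, click_level_change, msa_change, fled,
#'   resp_rate_change, tts_risk.
#' @param threshold magnitude threshold (percent, percentage points, or dB).
#' @return integer count.
#' @export
response_index <- function(cells, threshold = 8) {
  num <- function(v) !is.na(v) && abs(v) >= threshold
  flag <- function(v) isTRUE(as.logical(v))
  sum(flag(cells$startle), num(cells$crypsis_diff),
      num(cells$click_rate_change), num(cells$click_level_change),
      num(cells$msa_change), flag(cells$fled),
      num(cells$resp_rate_change), flag(cells$tts_risk))
}

#' Assemble a per-animal response row from stage outputs
#'
#' @param id animal/deployment label.
#' @param startle_calls data.frame from [detect_startle()] for the accepted
#'   pings considered (any TRUE among them counts as a startle).
#' @param crypsis_pre,crypsis_exp crypsis fractions (0-1) per window.
#' @param cpm_pre,cpm_exp click rates (cpm) per window; NA when clicks are
#'   not measurable.
#' @param lvl_pre,lvl_exp 95th-percentile click levels (dB pp); NA allowed.
#' @param effort_pre,effort_exp swimming-effort summaries (mean of
#'   95th-percentile MSA over 5-s bins) per window.
#' @param fled flag from [flight_flag()].
#' @param resp_pre,resp_exp respiration rates (per min) per window.
#' @param tts_risk flag from [cumulate_sel()].
#' @param index_threshold passed to [response_index()].
#' @return one-row data.frame of class `response_row`.
#' @export
build_response_row <- function(id, startle_calls, crypsis_pre, crypsis_exp,
                               cpm_pre, cpm_exp, lvl_pre, lvl_exp,
                               effort_pre, effort_exp, fled,
                               resp_pre, resp_exp, tts_risk,
                               index_threshold = 8) {
  startled <- any(startle_calls$startled %in% TRUE)
  cells <- data.frame(
    id = id,
    startle = startled,
    crypsis_diff = if (is.na(crypsis_pre) || is.na(crypsis_exp)) NA_real_
    else round_half_away(100 * (crypsis_exp - crypsis_pre)),
    click_rate_change = as.numeric(percent_change(cpm_pre, cpm_exp)),
    click_level_change = as.numeric(db_change(lvl_pre, lvl_exp)),
    msa_change = as.numeric(percent_change(effort_pre, effort_exp)),
    fled = as.logical(fled),
    resp_rate_change = as.numeric(percent_change(resp_pre, resp_exp)),
    tts_risk = isTRUE(tts_risk))
  cells$response_index <- response_index(cells, index_threshold)
  class(cells) <- c("response_row", "data.frame")
  cells
}

#' Run the full analysis pipeline on one deployment
#'
#' Orchestrates every stage on a [sensor_deployment()]: ping detection and
#' dosimetry, click/buzz metrics (when the audio rate allows), MSA/jerk and
#' startle, dives/crypsis, respirations, GPS kinematics, and the response
#' row comparing the exposure against the immediately preceding control
#' window. Cells whose input is unavailable (e.g. clicks on a mid-frequency
#' tag) are left undefined and excluded from the response index.
#'
#' @param dep a [sensor_deployment()] with exposure metadata.
#' @param snr_min ping acceptance SNR, dB.
#' @param tts_threshold,tts_margin passed to [cumulate_sel()].
#' @param bathymetry optional grid for [estimate_seafloor()].
#' @param index_threshold passed to [response_index()].
#' @param startle_pings number of initial accepted pings summarized into
#'   the startle flag.
#' @param ping_args,click_args extra arguments for [ping_detections()] /
#'   [detect_clicks()].
#' @return list with the stage outputs (`pings`, `dose`, `clicks`,
#'   `kinematics`, `dives`, `crypsis`, `respirations`, `track`, `windows`)
#'   and `response` (a [build_response_row()] row).
#' @export
analyze_deployment <- function(dep, snr_min = 10, tts_threshold = 142,
                               tts_margin = 3, bathymetry = NULL,
                               index_threshold = 8, startle_pings = 5,
                               ping_args = list(), click_args = list()) {
  if (is.null(dep$exposure)) stop("deployment has no exposure metadata")
  wp <- window_pair(dep$exposure)

  ## dosimetry
  pings <- do.call(ping_detections,
                   c(list(dep$audio, snr_min = snr_min), ping_args))
  exp_pings <- pings[pings$time >= wp$exposure[1] &
                       pings$time <= wp$exposure[2] + 5, , drop = FALSE]
  dose <- cumulate_sel(exp_pings, tts_threshold, tts_margin)

  ## echolocation (mid-frequency tags cannot resolve NBHF clicks)
  clicks <- NULL
  cpm <- c(NA_real_, NA_real_)
  lvl <- c(NA_real_, NA_real_)
  click_ok <- tryCatch({
    hp <- highpass_clicks(dep$audio$data, dep$audio$fs)
    TRUE
  }, error = function(e) FALSE)
  if (click_ok) {
    ct <- do.call(detect_clicks, c(list(hp, dep$audio$fs), click_args))
    ok <- ct > 0.011 & ct < length(hp) / dep$audio$fs - 0.011
    ct <- ct[ok]
    lv <- vapply(ct, function(t0)
      click_apparent_level(hp, dep$audio$fs, t0), 0)
    clicks <- data.frame(time = ct, level_pp = lv)
    cpm <- c(click_rate(ct, wp$pre), click_rate(ct, wp$exposure))
    lvl <- c(level_percentile(clicks, wp$pre),
             level_percentile(clicks, wp$exposure))
  }

  ## kinematics
  msa <- compute_msa(dep$accel$data, dep$accel$fs)
  jerk <- compute_jerk(dep$accel$data, dep$accel$fs)
  effort <- swimming_effort(msa)
  effort_t <- (seq_along(effort) - 0.5) * 5
  eff <- c(mean(effort[effort_t >= wp$pre[1] & effort_t < wp$pre[2]]),
           mean(effort[effort_t >= wp$exposure[1] &
                         effort_t < wp$exposure[2]]))
  first_acc <- utils::head(
    pings$time[pings$accepted & pings$time >= wp$exposure[1]], startle_pings)
  startle <- detect_startle(jerk, first_acc)

  ## dives, seafloor, crypsis
  dives <- segment_dives(dep$depth)
  seafloor <- estimate_seafloor(dives, dep$gps, bathymetry)
  cry <- crypsis_mask(dep$depth, seafloor)
  cry_frac <- c(crypsis_fraction(cry, wp$pre),
                crypsis_fraction(cry, wp$exposure))

  ## respirations
  resp <- detect_respirations(dep$audio, dep$depth)
  resp_rate <- c(respiration_rate(resp$time, wp$pre),
                 respiration_rate(resp$time, wp$exposure))

  ## track and flight
  track <- if (!is.null(dep$gps) && nrow(dep$gps) >= 2)
    leg_speeds(dep$gps) else NULL
  fled <- flight_flag(pings, wp$exposure, track,
                      dep$exposure$ahd_lat, dep$exposure$ahd_lon)

  response <- build_response_row(
    dep$deployment_id, startle, cry_frac[1], cry_frac[2],
    cpm[1], cpm[2], lvl[1], lvl[2], eff[1], eff[2], fled,
    resp_rate[1], resp_rate[2], dose$tts_risk,
    index_threshold = index_threshold)

  list(windows = wp, pings = pings, dose = dose, clicks = clicks,
       kinematics = list(msa = msa, jerk = jerk, effort = effort),
       startle = startle, dives = dives, seafloor = seafloor,
       crypsis = cry, respirations = resp, track = track,
       response = response)
}

#' Group summary across animals
#'
#' Arithmetic means over the defined values of the designated subsets:
#' swimming effort over the fleeing animals, click-rate change over the
#' animals that decreased their rate, crypsis difference over all animals
#' with defined cells, and travel speed over the supplied per-animal
#' percent increases (animals with GPS). Means are rounded half away from
#' zero to the nearest integer, the table's reporting precision.
#'
#' @param tables data.frame of stacked response rows.
#' @param speed_changes optional numeric vector of per-animal percent speed
#'   increases.
#' @return list with `mean_msa_change_fleeing`, `mean_click_rate_decrease`
#'   (magnitude of the mean change over decreasing animals),
#'   `mean_crypsis_diff`, `mean_speed_change`, and the subset sizes.
#' @export
summarize_group <- function(tables, speed_changes = NULL) {
  fleeing <- tables$fled %in% TRUE & !is.na(tables$msa_change)
  decreasing <- !is.na(tables$click_rate_change) & tables$click_rate_change < 0
  defined_cry <- !is.na(tables$crypsis_diff)
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else
    round_half_away(mean(v))
  list(
    mean_msa_change_fleeing = mean_or_na(tables$msa_change[fleeing]),
    n_fleeing = sum(fleeing),
    mean_click_rate_decrease = abs(mean_or_na(
      tables$click_rate_change[decreasing])),
    n_decreasing = sum(decreasing),
    mean_crypsis_diff = mean_or_na(tables$crypsis_diff[defined_cry]),
    n_crypsis = sum(defined_cry),
    mean_speed_change = if (is.null(speed_changes)) NA_real_ else
      mean_or_na(speed_changes),
    n_speed = length(speed_changes))
}
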