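# Echolocation clicks and feeding buzzes.
#
# Porpoises emit narrow-band high-frequency (NBHF, ~130 kHz) clicks; feeding
# buzzes are rapid terminal click sequences with inter-click intervals (ICI)
# below 15 ms accompanied by a rapid change in acceleration (which separates
# them from social calls with similar ICIs). Click apparent output level is
# the peak-to-peak sound pressure in a 20-ms segment around each detection,
# measured after an 80-kHz 6-pole high-pass; levels are "apparent" because
# they depend on tag placement and are never compared across deployments.

#' High-pass filter audio for click-level measurement
#'
#' 6-pole Butterworth high-pass at 80 kHz. Requires a sampling rate of at
#' least twice the NBHF click band (>= 260 kHz): on slower (mid-frequency)
#' tags the ~130 kHz clicks alias and cannot be measured reliably, so the
#' function refuses and suggests buzz-only analysis (buzzes remain visible
#' in spectrograms at those rates).
#'
#' @param x audio samples (Pa).
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass edge, Hz.
#' @param min_rate minimum sampling rate for reliable NBHF click work, Hz.
#' @return filtered samples.
#' @export
highpass_clicks <- function(x, fs, cutoff = 80000, min_rate = 260000) {
  if (fs < min_rate)
    stop("sampling rate ", fs, " Hz is too low for reliable NBHF click ",
         "detection (needs >= ", min_rate,
         " Hz); use buzz-only spectrogram analysis instead")
  bf <- signal::butter(6, cutoff / (fs / 2), type = "high")
  zero_phase(bf, x)
}

#' Detect echolocation clicks
#'
#' Automatic envelope detector standing in for a supervised click detector:
#' local envelope peaks exceeding the envelope median by `threshold_db` are
#' reported, with a minimum inter-detection gap of 1 ms (well below buzz
#' ICIs, so buzz clicks are individually resolved). An accept/reject review
#' table can reproduce the supervised step via [apply_review()].
#'
#' @param x high-passed audio (Pa).
#' @param fs sampling rate, Hz.
#' @param threshold_db detection threshold above the envelope median, dB.
#' @param min_gap minimum separation, s.
#' @param smooth envelope smoothing window, s.
#' @return numeric vector of click times, s.
#' @export
detect_clicks <- function(x, fs, threshold_db = 20, min_gap = 0.001,
                          smooth = 1e-4) {
  k <- max(2, round(smooth * fs))
  env <- sqrt(moving_sum(x^2, k) / k)
  thr <- stats::median(env[seq(1, length(env), by = max(1, length(env) %/% 1000000))]) *
    10^(threshold_db / 20)
  above <- env > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (length(rises) == 0) return(numeric(0))
  falls <- which(!above & c(FALSE, above[-length(above)]))
  times <- numeric(0)
  last <- -Inf
  fi <- 1
  for (r in rises) {
    while (fi <= length(falls) && falls[fi] <= r) fi <- fi + 1
    f <- if (fi <= length(falls)) falls[fi] else length(env) + 1
    pk <- r - 1 + which.max(env[r:(f - 1)])
    t_pk <- (pk - 1) / fs + k / (2 * fs)
    if (t_pk - last >= min_gap) {
      times <- c(times, t_pk)
      last <- t_pk
    }
  }
  times
}

#' Apparent click output level (peak-to-peak)
#'
#' `20 log10((max - min pressure) / 1 uPa)` over a 20-ms segment centred on
#' the detection.
#'
#' @param x high-passed audio (Pa).
#' @param fs sampling rate, Hz.
#' @param click_time detection time, s.
#' @param segment measurement segment length, s.
#' @return level in dB re 1 uPa peak-to-peak.
#' @export
click_apparent_level <- function(x, fs, click_time, segment = 0.02) {
  i0 <- round((click_time - segment / 2) * fs) + 1
  i1 <- i0 + round(segment * fs) - 1
  if (i0 < 1 || i1 > length(x))
    stop("measurement segment extends beyond the recording")
  seg <- x[i0:i1]
  pa_to_db(max(seg) - min(seg))
}

#' Click rate in a window
#'
#' @param times click times, s.
#' @param window length-2 interval `c(start, end)`, s.
#' @return clicks per minute.
#' @export
click_rate <- function(times, window) {
  len <- window[2] - window[1]
  if (len <= 0) stop("window length must be > 0")
  sum(times >= window[1] & times < window[2]) / (len / 60)
}

#' Percentile of apparent click levels in a window
#'
#' Linear-interpolation percentile (the 95th is the default: the maximum
#' output level is what matters for acoustic crypsis). Returns `NA` with
#' attribute `defined = FALSE` when the window holds no clicks, which
#' propagates as an undefined ("-") response-table cell.
#'
#' @param clicks data.frame with `time` and `level_pp`.
#' @param window length-2 interval, s (or `NULL` for all clicks).
#' @param q percentile in (0, 100].
#' @return level in dB re 1 uPa pp, or flagged `NA`.
#' @export
level_percentile <- function(clicks, window = NULL, q = 95) {
  lv <- if (is.null(window)) clicks$level_pp else
    clicks$level_pp[clicks$time >= window[1] & clicks$time < window[2]]
  if (length(lv) == 0) return(structure(NA_real_, defined = FALSE))
  structure(unname(stats::quantile(lv, q / 100, type = 7)), defined = TRUE)
}

#' Detect feeding buzzes
#'
#' Maximal runs of at least `min_run` clicks whose ICIs are all below
#' `ici_max`, accepted only when the jerk signal shows a transient (above
#' `jerk_gate`, default twice the deployment median jerk) within 1 s of the
#' run -- the movement criterion that excludes social calls.
#'
#' @param click_times click times, s (ordered).
#' @param jerk list with `jerk` (m/s^3) and `fs`, from [compute_jerk()].
#' @param ici_max maximum ICI inside a buzz, s.
#' @param min_run minimum clicks per buzz.
#' @param jerk_gate m/s^3; `NULL` for 2 x median jerk.
#' @param jerk_margin s searched around the run for the transient.
#' @return data.frame: start, end, n_clicks, max_jerk, accepted (TRUE rows
#'   only are buzzes; rejected ICI-runs are returned with accepted = FALSE).
#' @export
detect_buzzes <- function(click_times, jerk, ici_max = 0.015, min_run = 5,
                          jerk_gate = NULL, jerk_margin = 1) {
  if (is.unsorted(click_times)) stop("click times must be ordered")
  if (is.null(jerk_gate)) jerk_gate <- 2 * stats::median(jerk$jerk)
  ici <- diff(click_times)
  fast <- ici < ici_max
  out <- data.frame(start = numeric(0), end = numeric(0),
                    n_clicks = integer(0), max_jerk = numeric(0),
                    accepted = logical(0))
  if (!any(fast)) return(out)
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  jt <- (seq_along(jerk$jerk)) / jerk$fs
  for (i in which(r$values & r$lengths >= (min_run - 1))) {
    t0 <- click_times[starts[i]]
    t1 <- click_times[ends[i] + 1]
    sel <- jt >= t0 - jerk_margin & jt <= t1 + jerk_margin
    mj <- if (any(sel)) max(jerk$jerk[sel]) else 0
    out <- rbind(out, data.frame(start = t0, end = t1,
                                 n_clicks = r$lengths[i] + 1L,
                                 max_jerk = mj, accepted = mj > jerk_gate))
  }
  out
}

#' Time of resumption of feeding
#'
#' The time of the `n`-th feeding buzz strictly after `t0` (tagging or
#' exposure end); counting to the fifth buzz avoids sensitivity to single
#' mis-classified social calls. `NA` when fewer than `n` buzzes follow.
#'
#' @param buzzes data.frame from [detect_buzzes()] (accepted rows are used).
#' @param t0 reference time, s.
#' @param n which buzz marks resumption.
#' @return time in s, or `NA`.
#' @export
feeding_resumption <- function(buzzes, t0, n = 5) {
  if ("accepted" %in% names(buzzes))
    buzzes <- buzzes[buzzes$accepted, , drop = FALSE]
  after <- sort(buzzes$start[buzzes$start > t0])
  if (length(after) < n) NA_real_ else after[n]
}

#' Apply a manual review table to detections
#'
#' Reproduces the supervised verification step: `remove` times are matched
#' to the nearest detection (within `tol`) and dropped; `add` times are
#' inserted.
#'
#' @param times detection times, s.
#' @param add,remove numeric vectors of times, s.
#' @param tol matching tolerance for removals, s.
#' @return revised, sorted times.
#' @export
apply_review <- function(times, add = numeric(0), remove = numeric(0),
                         tol = 0.05) {
  for (r in remove) {
    if (length(times) == 0) break
    i <- which.min(abs(times - r))
    if (abs(times[i] - r) <= tol) times <- times[-i]
  }
  sort(c(times, add))
}

#' Spectrogram for buzz auditing
#'
#' Convenience export of the spectrogram parameters used for manual buzz
#' verification (Hamming window, FFT 512, 75% overlap) over a time slice.
#'
#' @param x audio samples (Pa).
#' @param fs sampling rate, Hz.
#' @param t0,t1 slice, s.
#' @return a `specgram` object from the signal package.
#' @export
buzz_audit_spectrogram <- function(x, fs, t0 = 0, t1 = length(x) / fs) {
  seg <- x[(round(t0 * fs) + 1):min(length(x), round(t1 * fs))]
  signal::specgram(seg, n = 512, Fs = fs, window = signal::hamming(512),
                   overlap = 384)
}
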