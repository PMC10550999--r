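# ECG processing: R-peaks and instantaneous heart rate.
#
# Tag ECG is down-sampled to 250 Hz and band-passed 1-10 Hz (4-pole), which
# suppresses baseline wander and electrode noise while keeping the QRS
# complex. Instantaneous heart rate fH is 60 / RR for each R-R interval,
# assigned at the interval's end (causal, which keeps event-locked analyses
# of post-ping tachycardia simple).

#' Preprocess ECG for R-peak detection
#'
#' @param ecg list with `data` (voltage) and `fs` (>= 250 Hz), or numeric
#'   vector with `fs` given.
#' @param fs native rate if `ecg` is a bare vector.
#' @param target_fs working rate, Hz.
#' @param band band-pass edges, Hz (4-pole Butterworth).
#' @return list with `data` (filtered), `fs`.
#' @export
preprocess_ecg <- function(ecg, fs = NULL, target_fs = 250, band = c(1, 10)) {
  if (is.list(ecg)) { fs <- ecg$fs; ecg <- ecg$data }
  if (fs < target_fs) stop("ECG rate must be >= ", target_fs, " Hz")
  if (fs > target_fs) {
    dec <- decimate_series(ecg, fs, target_fs)
    ecg <- dec$data
    fs <- dec$fs
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  list(data = zero_phase(bf, ecg), fs = fs)
}

#' Detect R-peaks
#'
#' Adaptive-threshold peak picking on the preprocessed ECG: the threshold is
#' `frac` of the running envelope maximum (5-s blocks), with a refractory
#' period of 0.25 s (supports rates up to 240 bpm). Peak times are refined
#' to sub-sample precision by parabolic interpolation. Beats can be added or
#' removed afterwards with [apply_review()], mirroring visual verification.
#'
#' @param ecg list from [preprocess_ecg()].
#' @param frac threshold as a fraction of the local envelope maximum.
#' @param refractory s.
#' @param block envelope-maximum block length, s.
#' @return numeric vector of R-peak times, s.
#' @export
detect_r_peaks <- function(ecg, frac = 0.5, refractory = 0.25, block = 5) {
  x <- ecg$data
  fs <- ecg$fs
  n <- length(x)
  a <- abs(x)
  per <- max(1, floor(block * fs))
  n_blocks <- ceiling(n / per)
  blk_max <- vapply(seq_len(n_blocks), function(b) {
    max(a[((b - 1) * per + 1):min(n, b * per)])
  }, 0)
  # filter edge transients can inflate a single block; cap against the
  # typical envelope so boundary blocks keep detecting real beats
  blk_max <- pmin(blk_max, 1.5 * stats::median(blk_max))
  thr_local <- frac * blk_max[pmin(n_blocks, ceiling(seq_len(n) / per))]
  cand <- which(x > thr_local &
                  x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
  if (length(cand) == 0) return(numeric(0))
  peaks <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    t_i <- (i - 1) / fs
    if (t_i - last_t >= refractory) {
      peaks <- c(peaks, i)
      last_t <- t_i
    } else if (length(peaks) > 0 && x[i] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i            # keep the larger of close peaks
      last_t <- t_i
    }
  }
  # parabolic sub-sample refinement
  vapply(peaks, function(i) {
    if (i <= 1 || i >= n) return((i - 1) / fs)
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    den <- y0 - 2 * y1 + y2
    d <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
    (i - 1 + max(-0.5, min(0.5, d))) / fs
  }, 0)
}

#' Instantaneous heart rate from R-peak times
#'
#' `fH = 60 / RR`, assigned at the end of each R-R interval.
#'
#' @param r_times R-peak times, s (strictly increasing).
#' @return data.frame of class `heartbeat_series`: time, rr (s), fh (bpm).
#' @export
instantaneous_fh <- function(r_times) {
  if (length(r_times) >= 2 && any(diff(r_times) <= 0))
    stop("R-peak times must be strictly increasing")
  if (length(r_times) < 2) {
    return(structure(data.frame(time = numeric(0), rr = numeric(0),
                                fh = numeric(0)),
                     class = c("heartbeat_series", "data.frame")))
  }
  rr <- diff(r_times)
  structure(data.frame(time = r_times[-1], rr = rr, fh = 60 / rr),
            class = c("heartbeat_series", "data.frame"))
}

#' Summarize heart rate per window and as a running median
#'
#' Per labelled window: 10th/90th percentiles and median of fH. The running
#' median uses a centred `median_win` (50 s) window over the irregular beat
#' times.
#'
#' @param fh a `heartbeat_series` from [instantaneous_fh()].
#' @param windows data.frame with label, start, end (s).
#' @param median_win running-median window, s.
#' @return list with `windows` (label, n, p10, median, p90; NA when empty)
#'   and `running` (time, fh_median).
#' @export
fh_summary <- function(fh, windows = NULL, median_win = 50) {
  win_tab <- NULL
  if (!is.null(windows)) {
    win_tab <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
      v <- fh$fh[fh$time >= windows$start[i] & fh$time < windows$end[i]]
      if (length(v) == 0) {
        data.frame(label = windows$label[i], n = 0L, p10 = NA_real_,
                   median = NA_real_, p90 = NA_real_)
      } else {
        q <- stats::quantile(v, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
        data.frame(label = windows$label[i], n = length(v), p10 = q[1],
                   median = q[2], p90 = q[3])
      }
    }))
  }
  running <- data.frame(time = fh$time, fh_median = vapply(fh$time, function(t0) {
    stats::median(fh$fh[fh$time >= t0 - median_win / 2 &
                          fh$time <= t0 + median_win / 2])
  }, 0))
  list(windows = win_tab, running = running)
}
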