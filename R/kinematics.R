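# Accelerometry: MSA, jerk and acoustic startle detection.
#
# Minimum specific acceleration (MSA) is |norm(a) - g|, a lower bound on the
# specific (non-gravitational) acceleration that needs no orientation
# correction; its 95th percentile over 5-s bins proxies swimming effort.
# Jerk is the norm of the differentiated triaxial acceleration at 25 Hz;
# sharp jerk transients mark prey captures and the whole-body flinch of the
# acoustic startle reflex, which appears within 0.2 s of a received ping.

#' Minimum specific acceleration
#'
#' Triaxial acceleration is decimated to 25 Hz and MSA computed as
#' `|  ||a|| - g |`. Invariant under rotation of the tag frame.
#'
#' @param accel n x 3 matrix, m/s^2.
#' @param fs native sampling rate, Hz (>= 50).
#' @param decimate_to working rate, Hz.
#' @param g gravitational acceleration, m/s^2.
#' @return list with `msa` (m/s^2), `fs`.
#' @export
compute_msa <- function(accel, fs, decimate_to = 25, g = 9.81) {
  if (fs < 50) stop("accelerometer rate must be >= 50 Hz")
  dec <- decimate_series(accel, fs, decimate_to)
  norm3 <- sqrt(rowSums(dec$data^2))
  list(msa = abs(norm3 - g), fs = dec$fs)
}

#' Swimming effort: binned MSA percentile
#'
#' 95th percentile of MSA over consecutive bins (5 s, i.e. 125 samples at
#' 25 Hz).
#'
#' @param msa list from [compute_msa()] (or numeric vector with `fs`).
#' @param fs sampling rate if `msa` is a bare vector.
#' @param bin bin length, s.
#' @param q percentile in (0, 100].
#' @return numeric vector, one value per complete bin.
#' @export
swimming_effort <- function(msa, fs = NULL, bin = 5, q = 95) {
  if (is.list(msa)) { fs <- msa$fs; msa <- msa$msa }
  per <- floor(bin * fs)
  n_bins <- floor(length(msa) / per)
  if (n_bins == 0) return(numeric(0))
  m <- matrix(msa[seq_len(n_bins * per)], nrow = per)
  apply(m, 2, stats::quantile, probs = q / 100, type = 7, names = FALSE)
}

#' Jerk from triaxial acceleration
#'
#' Norm of the first difference of the decimated (25 Hz) acceleration,
#' scaled by the rate: `jerk[i] = ||a[i] - a[i-1]|| * fs`. The i-th jerk
#' sample is assigned time `i / fs`.
#'
#' @inheritParams compute_msa
#' @return list with `jerk` (m/s^3), `fs`, `times` (s).
#' @export
compute_jerk <- function(accel, fs, decimate_to = 25) {
  if (fs < 50) stop("accelerometer rate must be >= 50 Hz")
  dec <- decimate_series(accel, fs, decimate_to)
  d <- diff(dec$data)
  j <- sqrt(rowSums(d^2)) * dec$fs
  list(jerk = j, fs = dec$fs, times = seq_along(j) / dec$fs)
}

#' Detect acoustic startle responses against ping times
#'
#' A ping elicits a startle when the jerk peak inside `(ping, ping +
#' window]` exceeds the baseline mean + `k` standard deviations, with the
#' baseline taken over the `baseline` seconds preceding the ping. Pings with
#' insufficient pre-roll are flagged unevaluable rather than classified.
#'
#' @param jerk list from [compute_jerk()].
#' @param ping_times ping arrival times at the tag, s.
#' @param window startle window after the ping, s.
#' @param baseline baseline span before the ping, s.
#' @param k gate in baseline standard deviations.
#' @return data.frame: ping_time, startled, peak_jerk, latency, evaluable.
#' @export
detect_startle <- function(jerk, ping_times, window = 0.2, baseline = 10,
                           k = 3) {
  if (length(ping_times) == 0) {
    return(data.frame(ping_time = numeric(0), startled = logical(0),
                      peak_jerk = numeric(0), latency = numeric(0),
                      evaluable = logical(0)))
  }
  jt <- jerk$times
  out <- lapply(ping_times, function(p) {
    base <- jerk$jerk[jt >= p - baseline & jt < p]
    win <- which(jt > p & jt <= p + window)
    if (length(base) < baseline * jerk$fs * 0.9 || length(win) == 0) {
      return(data.frame(ping_time = p, startled = NA, peak_jerk = NA_real_,
                        latency = NA_real_, evaluable = FALSE))
    }
    gate <- mean(base) + k * stats::sd(base)
    pk <- win[which.max(jerk$jerk[win])]
    data.frame(ping_time = p, startled = jerk$jerk[pk] > gate,
               peak_jerk = jerk$jerk[pk], latency = jt[pk] - p,
               evaluable = TRUE)
  })
  do.call(rbind, out)
}

#' Warn about possible tag slides
#'
#' Compares the mean acceleration direction (dominated by gravity) between
#' consecutive windows; a rotation beyond `max_angle` suggests the tag slid
#' on the animal and level/effort comparisons across the slide are suspect.
#'
#' @param accel n x 3 matrix, m/s^2.
#' @param fs sampling rate, Hz.
#' @param window comparison window, s.
#' @param max_angle degrees.
#' @return data.frame of windows with the rotation angle and a `suspect`
#'   flag; warns when any window is suspect.
#' @export
check_tag_slide <- function(accel, fs, window = 300, max_angle = 20) {
  per <- floor(window * fs)
  n <- floor(nrow(accel) / per)
  if (n < 2) return(data.frame(time = numeric(0), angle = numeric(0),
                               suspect = logical(0)))
  dirs <- t(vapply(seq_len(n), function(i) {
    v <- colMeans(accel[((i - 1) * per + 1):(i * per), , drop = FALSE])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  ang <- c(NA, acos(pmin(1, rowSums(dirs[-1, , drop = FALSE] *
                                      dirs[-n, , drop = FALSE]))) * 180 / pi)
  res <- data.frame(time = (seq_len(n) - 1) * window, angle = ang,
                    suspect = !is.na(ang) & ang > max_angle)
  if (any(res$suspect))
    warning("possible tag slide: orientation rotated > ", max_angle,
            " degrees between windows")
  res
}
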