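#' Convert sound pressure in pascal to dB re 1 uPa
#'
#' All acoustic levels in this package are referenced to 1 uPa, the standard
#' underwater reference pressure. Pressures are stored internally in pascal,
#' and every dB conversion goes through this pair of helpers so that the
#' reference appears in exactly one place.
#'
#' @param p sound pressure in Pa (rms, peak or peak-to-peak depending on the
#'   quantity being expressed). Must be > 0 for a finite result.
#' @return level in dB re 1 uPa.
#' @seealso [db_to_pa()]
#' @export
#' @examples
#' pa_to_db(1)           # 120 dB re 1 uPa
#' db_to_pa(pa_to_db(0.02))
pa_to_db <- function(p) {
  20 * log10(p) + 120
}

#' Convert a level in dB re 1 uPa to pascal
#'
#' @param db level in dB re 1 uPa.
#' @return pressure in Pa.
#' @export
db_to_pa <- function(db) {
  10^((db - 120) / 20)
}

#' Root-mean-square of a numeric vector
#'
#' @param x numeric vector.
#' @return scalar rms.
#' @export
rms <- function(x) {
  sqrt(mean(x^2))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percent changes use
#' conventional half-away-from-zero rounding (so +31.25 reports as +31 and
#' -15.5 as -16).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# moving sum over a k-sample window via cumulative sums; returns a vector of
# length length(x) - k + 1 (window starting at each sample)
moving_sum <- function(x, k) {
  n <- length(x)
  if (k > n) stop("window longer than series")
  cs <- cumsum(x)
  cs[k:n] - c(0, cs[seq_len(n - k)])
}
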