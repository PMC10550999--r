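# Fast IIR filtering.
#
# Filter coefficients come from signal::butter; the filtering itself runs
# through stats::filter (compiled convolution + recursion), which keeps
# multi-minute high-rate audio tractable. Zero-phase filtering is the usual
# forward-backward pass (squared magnitude response, no group delay), used
# for level measurement; single-pass causal filtering is used where onset
# timing matters.

# apply an ARMA filter (list with $b, $a as from signal::butter) causally
arma_filter <- function(filt, x) {
  iir_filter_cpp(filt$b, filt$a, x)
}

# forward-backward (zero-phase) application of the same filter, with
# reflected edge padding to suppress start-up transients
zero_phase <- function(filt, x) {
  n <- length(x)
  np <- min(n - 1, 30 * max(length(filt$a), length(filt$b)))
  if (np > 0) {
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- rev(arma_filter(filt, rev(arma_filter(filt, xp))))
  if (np > 0) y[(np + 1):(np + n)] else y
}
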