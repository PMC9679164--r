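#' Canonical double-gamma haemodynamic response function
#'
#' The kernel linking neural drive to the BOLD signal, sampled at TR
#' resolution: a positive gamma density peaking at `peak_s` minus a scaled
#' gamma undershoot peaking at `undershoot_s`, truncated at `duration_s` and
#' normalized to unit sum (response amplitude is a free fit parameter).
#'
#' @param tr_s Sampling interval (s).
#' @param peak_s Time-to-peak of the positive lobe (s, default 6).
#' @param undershoot_s Time-to-peak of the undershoot (s, default 16).
#' @param undershoot_ratio Undershoot amplitude relative to the peak lobe
#'   (default 1/6).
#' @param duration_s Kernel support (s, default 32).
#' @return Numeric kernel of `duration_s / tr_s + 1` samples, class `hrf`.
#' @export
hrf_double_gamma <- function(tr_s = 1, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6, duration_s = 32) {
  t <- seq(0, duration_s, by = tr_s)
  # unit-rate gamma densities: shape = peak time + 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  s <- sum(h)
  if (s <= 0) stop("degenerate HRF: kernel sum is not positive")
  structure(h / s, class = "hrf", tr_s = tr_s)
}

# causal convolution of a drive vector with the HRF, truncated to length(x)
convolve_hrf <- function(x, hrf) {
  n <- length(x)
  stats::convolve(x, rev(hrf), type = "open")[seq_len(n)]
}
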