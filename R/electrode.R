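#' Invert per-maneuver RMS features into per-electrode RMS targets
#'
#' Given a maneuver's MeanRMS and MaxRMS over its agonist electrode set,
#' construct `k` per-electrode RMS values whose maximum equals the
#' (consistency-clipped) MaxRMS and whose arithmetic mean equals MeanRMS.
#' When `max_rms < mean_rms` — impossible for a max and mean over the same
#' electrodes, but present in the published summary for elbow extension —
#' the max is clipped up to the mean with a warning, so rendered signals stay
#' physically consistent while tabular marginals remain as published.
#'
#' For `k = 2` the solution is unique: `{2*mean - max', max'}`. For `k = 3`
#' the two non-maximal electrodes share `3*mean - max'` in equal halves with
#' up to 5% multiplicative jitter drawn from the caller's RNG stream, capped
#' so neither exceeds the maximum.
#'
#' @param mean_rms MeanRMS target (mV), > 0.
#' @param max_rms MaxRMS target (mV).
#' @param k agonist electrode count, 2 or 3.
#' @return Numeric vector of `k` per-electrode RMS values (mV), maximum first.
#' @examples
#' derive_electrode_rms(0.5, 0.7, k = 2) # c(0.7, 0.3)
#' @export
derive_electrode_rms <- function(mean_rms, max_rms, k) {
  stopifnot(length(mean_rms) == 1, length(max_rms) == 1)
  if (!k %in% c(2, 3)) stop("k must be 2 or 3")
  if (mean_rms <= 0) stop("mean_rms must be > 0")
  mx <- max_rms
  if (mx < mean_rms) {
    warning(sprintf(
      "max_rms (%.4g) below mean_rms (%.4g); clipped up to the mean", mx, mean_rms))
    mx <- mean_rms
  }
  if (k == 2) {
    other <- 2 * mean_rms - mx
    if (other <= 0)
      stop("infeasible electrode set: 2*mean_rms - max_rms <= 0")
    return(c(mx, other))
  }
  s <- 3 * mean_rms - mx
  if (s <= 0) stop("infeasible electrode set: 3*mean_rms - max_rms <= 0")
  # cap jitter so neither share exceeds the maximum (and both stay > 0)
  j_amp <- min(0.05, max(0, 2 * mx / s - 1))
  j <- runif(1, -1, 1) * j_amp
  a <- s / 2 * (1 + j)
  c(mx, a, s - a)
}
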