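#' Band-pass filter specification
#'
#' Defaults follow the recording pipeline: a 100–500 Hz Butterworth band-pass
#' of order 4, applied forward-backward (zero phase) to avoid group-delay bias
#' in short 3-s contraction windows.
#'
#' @param low_cut,high_cut band edges in Hz.
#' @param order Butterworth design order (per section; the band-pass has
#'   `2*order` poles).
#' @param apply_mode `"zero_phase"` (filtfilt) or `"causal"` (single pass).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 100, high_cut = 500, order = 4,
                        apply_mode = c("zero_phase", "causal")) {
  apply_mode <- match.arg(apply_mode)
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 apply_mode = apply_mode), class = "filter_spec")
}

#' RMS analysis window, in seconds relative to trial start
#'
#' The recording protocol does not prescribe an RMS window; the package
#' default excludes 0.25 s at each trace edge (force ramp-up/down and filter
#' transients) and evaluates the RMS over the remaining interior.
#'
#' @param start,end window bounds in seconds; samples with
#'   `start <= t < end` are used.
#' @return An `analysis_window` list.
#' @export
analysis_window <- function(start, end) {
  stopifnot(start >= 0, end > start)
  structure(list(start = start, end = end), class = "analysis_window")
}

default_window <- function(duration, edge = 0.25) {
  analysis_window(edge, duration - edge)
}

#' Band-pass filter an sEMG trace
#'
#' Butterworth band-pass (see [filter_spec()]); zero-phase mode runs the
#' filter forward and backward so the pass band has unit gain squared in
#' magnitude and no phase distortion.
#'
#' @param trace numeric sampled voltage series (mV).
#' @param sampling_rate sampling frequency in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered trace, same length as input.
#' @examples
#' t <- seq(0, 1, by = 1 / 4096)
#' x <- sin(2 * pi * 300 * t)
#' y <- bandpass_filter(x, 4096)
#' @export
bandpass_filter <- function(trace, sampling_rate, spec = filter_spec()) {
  nyq <- sampling_rate / 2
  if (spec$high_cut >= nyq)
    stop("high_cut must lie below the Nyquist frequency (", nyq, " Hz)")
  if (spec$low_cut <= 0) stop("low_cut must be > 0")
  # rough impulse-response span of the high-pass edge: order cycles at low_cut
  span <- ceiling(spec$order * sampling_rate / spec$low_cut)
  if (length(trace) < 3 * span)
    stop("trace too short for stable filtering (need >= ", 3 * span, " samples)")
  bt <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  if (spec$apply_mode == "zero_phase") {
    # symmetrized forward-backward pass: makes zero-phase filtering commute
    # exactly with time reversal (plain filtfilt pads only one end, leaving
    # direction-dependent edge transients)
    a <- as.numeric(signal::filtfilt(bt, trace))
    b <- rev(as.numeric(signal::filtfilt(bt, rev(trace))))
    (a + b) / 2
  } else {
    as.numeric(signal::filter(bt, trace))
  }
}

#' Full-wave rectify a trace
#'
#' Elementwise absolute value. Rectification leaves the RMS unchanged
#' (`|x|^2 = x^2`); it is kept as an explicit pipeline stage for fidelity to
#' the recording protocol.
#'
#' @param trace numeric series.
#' @return `abs(trace)`.
#' @export
rectify <- function(trace) abs(trace)

#' Root-mean-square amplitude over an analysis window
#'
#' @param trace numeric sampled series (mV).
#' @param sampling_rate sampling frequency in Hz.
#' @param window an [analysis_window()]; samples at times
#'   `start <= (i-1)/fs < end` enter the RMS.
#' @return `sqrt(mean(x^2))` over the window, in mV.
#' @examples
#' compute_rms(c(3, 4), 1, analysis_window(0, 2)) # sqrt(25/2)
#' @export
compute_rms <- function(trace, sampling_rate, window) {
  t <- (seq_along(trace) - 1) / sampling_rate
  idx <- t >= window$start & t < window$end
  if (sum(idx) < 2) stop("analysis window contains fewer than 2 samples")
  sqrt(mean(trace[idx]^2))
}

#' Process one recorded trial into per-electrode RMS amplitudes
#'
#' Applies the protocol pipeline — band-pass filter, full-wave rectification,
#' RMS — to every electrode trace of a trial.
#'
#' @param signals a `trial_signals` object (see [render_trial_signals()] or
#'   [read_signals()]).
#' @param spec a [filter_spec()].
#' @param window an [analysis_window()]; default excludes 0.25 s per edge.
#' @return Named numeric vector: electrode id -> RMS (mV).
#' @export
process_trial <- function(signals, spec = filter_spec(), window = NULL) {
  stopifnot(inherits(signals, "trial_signals"))
  if (is.null(window)) window <- default_window(signals$duration)
  fs <- signals$sampling_rate
  vapply(colnames(signals$traces), function(el) {
    x <- bandpass_filter(signals$traces[, el], fs, spec)
    compute_rms(rectify(x), fs, window)
  }, numeric(1))
}
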