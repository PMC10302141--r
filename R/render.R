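new_trial_signals <- function(subject_id, maneuver, trial_index, sampling_rate,
                              duration, traces, force, is_mvc = FALSE) {
  stopifnot(is.matrix(traces), nrow(traces) == round(duration * sampling_rate),
            sampling_rate >= 1000)
  structure(list(subject_id = subject_id, maneuver = maneuver,
                 trial_index = trial_index, sampling_rate = sampling_rate,
                 duration = duration, traces = traces, force = force,
                 is_mvc = is_mvc),
            class = "trial_signals")
}

#' @export
print.trial_signals <- function(x, ...) {
  cat(sprintf("sEMG trial: %s %s trial %d%s | %d electrodes x %d samples @ %g Hz | force %.2f kg\n",
              x$subject_id, x$maneuver, x$trial_index,
              if (x$is_mvc) " (MVC)" else "", ncol(x$traces), nrow(x$traces),
              x$sampling_rate, x$force))
  invisible(x)
}

#' Render raw multi-electrode sEMG trials for one synthetic subject-maneuver
#'
#' Forward model for the synthetic cohort: produces three isometric-trial
#' recordings whose processed output (band-pass, rectify, RMS over the
#' analysis window) reproduces the subject row's MeanRMS, MaxRMS and RatioRMS
#' for the maneuver. Each electrode trace is zero-mean Gaussian noise
#' band-limited to an interior 180–420 Hz slice of the 100–500 Hz recording
#' band, rescaled so its windowed RMS matches its [derive_electrode_rms()]
#' target exactly; antagonist electrodes each receive RMS
#' `mean_rms / ratio_rms`. The interior band keeps the recording band-pass
#' transparent on reprocessing: noise shaped by the recording filter itself
#' would lose about 5% RMS to the filter's own skirts on a second pass,
#' whereas the interior band loses under 1%. A 0.25-s silent ramp pads each end
#' of the contraction and is excluded from the analysis window, so the stored
#' trace duration is `duration + 0.5` s. One trial (chosen from the seeded
#' stream) carries the row's MVC strength; the other trials are submaximal
#' copies with force and RMS targets scaled by a factor in \[0.85, 0.98\].
#'
#' @param row single-row cohort data.frame (see [sample_cohort()]).
#' @param maneuver one of `"EF"`, `"EE"`, `"KF"`, `"KE"`.
#' @param montage electrode montage, default [study_montage()].
#' @param sampling_rate Hz, >= 1024 (default 4096: Nyquist-sufficient for the
#'   500 Hz band edge at desk scale).
#' @param duration contraction duration in s (protocol: 3 s).
#' @param n_trials trials to render (protocol: 3 valid trials).
#' @param seed master integer seed; trials draw from child streams keyed by
#'   subject, maneuver and trial index.
#' @return List of `n_trials` `trial_signals` objects.
#' @examples
#' coh <- sample_cohort(1, seed = 4)
#' tr <- render_trial_signals(coh[1, ], "KF", seed = 4)
#' process_trial(tr[[1]])
#' @export
render_trial_signals <- function(row, maneuver, montage = study_montage(),
                                 sampling_rate = 4096, duration = 3,
                                 n_trials = 3, seed = 1) {
  stopifnot(nrow(row) == 1, maneuver %in% MANEUVERS,
            sampling_rate >= 1024, duration > 0, n_trials >= 1)
  check_montage(montage)
  mo <- montage[[maneuver]]
  pad <- 0.25
  total <- duration + 2 * pad
  n <- round(total * sampling_rate)
  window <- analysis_window(pad, pad + duration)
  # render inside the recording band so reprocessing is gain-transparent
  render_spec <- filter_spec(180, 420, order = 6)

  mean_rms <- row[[paste0("mean_rms_", maneuver)]]
  max_rms <- row[[paste0("max_rms_", maneuver)]]
  ratio <- row[[paste0("ratio_rms_", maneuver)]]
  mvc <- row[[paste0("mvc_strength_", maneuver)]]
  if (ratio <= 0) stop("ratio_rms must be > 0")

  set.seed(child_seed(seed, paste(row$subject_id, maneuver, "electrodes", sep = "/")))
  ago_targets <- setNames(derive_electrode_rms(mean_rms, max_rms,
                                               k = length(mo$agonist)),
                          mo$agonist)
  ant_targets <- setNames(rep(mean_rms / ratio, length(mo$antagonist)),
                          mo$antagonist)
  targets <- c(ago_targets, ant_targets)

  mvc_trial <- sample.int(n_trials, 1)
  scales <- runif(n_trials, 0.85, 0.98)
  scales[mvc_trial] <- 1

  envelope <- rep(1, n)
  npad <- round(pad * sampling_rate)
  envelope[seq_len(npad)] <- seq(0, 1, length.out = npad)
  envelope[n - npad + seq_len(npad)] <- seq(1, 0, length.out = npad)

  lapply(seq_len(n_trials), function(tr) {
    set.seed(child_seed(seed, paste(row$subject_id, maneuver, tr, sep = "/")))
    traces <- vapply(names(targets), function(el) {
      x <- bandpass_filter(rnorm(n), sampling_rate, render_spec) * envelope
      x * (targets[[el]] * scales[tr] / compute_rms(x, sampling_rate, window))
    }, numeric(n))
    colnames(traces) <- names(targets)
    new_trial_signals(row$subject_id, maneuver, tr, sampling_rate, total,
                      traces, force = mvc * scales[tr],
                      is_mvc = tr == mvc_trial)
  })
}
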