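#' Maximal voluntary contraction strength from three trial forces
#'
#' The protocol records three valid isometric trials per maneuver and takes
#' the maximum force as MVC strength; ties go to the earliest trial.
#'
#' @param forces numeric vector of exactly three trial forces (kg), all > 0.
#' @return List with `mvc_strength` (kg) and `trial_index`.
#' @examples
#' mvc_strength(c(18.2, 19.7, 19.1))
#' @export
mvc_strength <- function(forces) {
  if (length(forces) != 3)
    stop("protocol requires exactly three valid trials, got ", length(forces))
  if (any(forces <= 0)) stop("all trial forces must be > 0")
  i <- which.max(forces)
  list(mvc_strength = forces[i], trial_index = i)
}

#' Per-maneuver RMS features from a per-electrode RMS map
#'
#' MeanRMS and MaxRMS are the arithmetic mean and maximum of the per-electrode
#' RMS over the maneuver's agonist set; RatioRMS divides MeanRMS by the mean
#' RMS over the antagonist set recorded during the same maneuver (an
#' agonist/antagonist co-contraction ratio).
#'
#' @param per_electrode_rms named numeric vector, electrode id -> RMS (mV).
#' @param montage electrode montage, default [study_montage()].
#' @param maneuver one of `"EF"`, `"EE"`, `"KF"`, `"KE"`.
#' @return List with `maneuver`, `mean_rms`, `max_rms`, `ratio_rms`.
#' @examples
#' maneuver_features(c("1" = 0.6, "2" = 0.7, "3" = 0.65, "4" = 0.3, "5" = 0.35),
#'                   maneuver = "EF")
#' @export
maneuver_features <- function(per_electrode_rms, montage = study_montage(),
                              maneuver) {
  stopifnot(maneuver %in% MANEUVERS)
  mo <- montage[[maneuver]]
  need <- c(mo$agonist, mo$antagonist)
  miss <- setdiff(need, names(per_electrode_rms))
  if (length(miss))
    stop("missing electrode(s) for ", maneuver, ": #",
         paste(miss, collapse = ", #"))
  v <- per_electrode_rms[need]
  if (any(v < 0)) stop("RMS values must be >= 0")
  ago <- per_electrode_rms[mo$agonist]
  ant <- per_electrode_rms[mo$antagonist]
  if (mean(ant) == 0) stop("antagonist mean RMS is zero; ratio undefined")
  list(maneuver = maneuver,
       mean_rms = mean(ago),
       max_rms = max(ago),
       ratio_rms = mean(ago) / mean(ant))
}

#' Select the trial whose RMS features are reported
#'
#' The reported features are taken from the maximal-force (MVC) trial,
#' consistent with the MVC strength definition; ties go to the earliest trial.
#'
#' @param trials list of trials, each with a `force` element.
#' @return Index of the selected trial.
#' @export
select_feature_trial <- function(trials) {
  if (!length(trials)) stop("at least one processed trial required")
  which.max(vapply(trials, `[[`, numeric(1), "force"))
}

#' Full feature set for one subject-maneuver from raw trials
#'
#' Processes every trial (filter, rectify, RMS), takes MVC strength as the
#' max force over trials, and computes the RMS features from the MVC trial.
#'
#' @param trials list of `trial_signals` for one subject-maneuver
#'   (3 trials per protocol).
#' @param montage electrode montage.
#' @param spec a [filter_spec()].
#' @param window an [analysis_window()] or NULL for the default.
#' @return List with `maneuver`, `mean_rms`, `max_rms`, `ratio_rms`,
#'   `mvc_strength`, `source_trial_index`.
#' @export
subject_features <- function(trials, montage = study_montage(),
                             spec = filter_spec(), window = NULL) {
  stopifnot(length(trials) >= 1)
  maneuver <- trials[[1]]$maneuver
  forces <- vapply(trials, `[[`, numeric(1), "force")
  strength <- if (length(trials) == 3) mvc_strength(forces)
              else list(mvc_strength = max(forces), trial_index = which.max(forces))
  sel <- select_feature_trial(trials)
  rms <- process_trial(trials[[sel]], spec = spec, window = window)
  feat <- maneuver_features(rms, montage, maneuver)
  c(feat, list(mvc_strength = strength$mvc_strength, source_trial_index = sel))
}
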