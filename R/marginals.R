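#' Built-in study marginal specifications
#'
#' Mean, SD and physical lower bound for every continuous cohort variable, as
#' reported for the study cohort (total n = 212, model-development n = 137,
#' cross-validation n = 75). Units: years (age), m (height), kg (weight, ASM,
#' BFM, segmental masses, MVC strength), mV (RMS amplitudes), mm (muscle
#' thickness); RatioRMS is dimensionless.
#'
#' Two reported values need comment. The total-cohort RatioRMS(EE) mean is
#' taken as 1.44 — consistent with the group values 1.44/1.43 — rather than
#' the internally inconsistent 2.44 that appears in the source table. The
#' reported MaxRMS(EE) mean (0.31 mV) lies below MeanRMS(EE) (0.73 mV), which
#' cannot hold for a max and mean over the same electrodes; the marginals are
#' emitted as reported and the inconsistency is resolved only at signal
#' rendering time (see [derive_electrode_rms()]).
#'
#' Segmental lean/fat mass marginals for the dominant arm and leg are not
#' reported and are package assumptions consistent with the cohort's ASM
#' (see the methods vignette).
#'
#' @param group `"total"`, `"development"` or `"validation"`.
#' @return A data.frame with columns `variable`, `mean`, `sd`, `lower`.
#' @seealso [study_sex_fraction()], [sample_cohort()]
#' @examples
#' head(study_marginals("total"))
#' @export
study_marginals <- function(group = c("total", "development", "validation")) {
  group <- match.arg(group)
  # columns: total mean/sd, development mean/sd, validation mean/sd
  tab <- rbind(
    age             = c(59,    11,   61,    10,   57,    10),
    height          = c(1.62,  0.08, 1.62,  0.09, 1.63,  0.08),
    weight          = c(64.6,  11.2, 64.5,  10.8, 64.9,  12.0),
    asm             = c(18.95, 4.56, 18.83, 4.56, 19.18, 4.59),
    bfm             = c(18.75, 5.84, 18.85, 6.23, 18.55, 5.10),
    slm_arm         = c(2.4,   0.7,  2.4,   0.7,  2.4,   0.7),
    slm_leg         = c(7.1,   1.7,  7.1,   1.7,  7.1,   1.7),
    sfm_arm         = c(1.2,   0.5,  1.2,   0.5,  1.2,   0.5),
    sfm_leg         = c(3.0,   1.0,  3.0,   1.0,  3.0,   1.0),
    thickness_bb    = c(13.91, 3.03, 13.82, 2.84, 14.08, 3.36),
    thickness_tb    = c(10.61, 3.51, 10.52, 3.52, 10.79, 3.51),
    thickness_bf    = c(19.09, 4.51, 19.05, 4.35, 19.15, 4.81),
    thickness_rf    = c(11.26, 2.51, 11.11, 2.45, 11.53, 2.61),
    mvc_strength_EF = c(19.7,  6.2,  19.6,  6.3,  19.9,  6.2),
    mvc_strength_EE = c(13.8,  4.3,  13.9,  4.5,  13.6,  4.0),
    mvc_strength_KF = c(13.0,  4.3,  12.8,  4.2,  13.3,  4.3),
    mvc_strength_KE = c(24.0,  8.2,  24.2,  8.4,  23.6,  7.9),
    mean_rms_EF     = c(0.66,  0.27, 0.66,  0.28, 0.65,  0.24),
    mean_rms_EE     = c(0.73,  0.30, 0.74,  0.30, 0.70,  0.30),
    mean_rms_KF     = c(0.32,  0.13, 0.32,  0.13, 0.32,  0.13),
    mean_rms_KE     = c(0.23,  0.10, 0.23,  0.10, 0.23,  0.10),
    max_rms_EF      = c(0.72,  0.30, 0.72,  0.31, 0.73,  0.28),
    max_rms_EE      = c(0.31,  0.13, 0.30,  0.13, 0.33,  0.14),
    max_rms_KF      = c(0.37,  0.16, 0.37,  0.16, 0.38,  0.16),
    max_rms_KE      = c(0.25,  0.11, 0.25,  0.10, 0.26,  0.11),
    ratio_rms_EF    = c(2.30,  0.69, 2.36,  0.73, 2.20,  0.61),
    ratio_rms_EE    = c(1.44,  0.42, 1.44,  0.38, 1.43,  0.48),
    ratio_rms_KF    = c(2.53,  0.98, 2.57,  0.96, 2.45,  1.01),
    ratio_rms_KE    = c(1.88,  0.63, 1.87,  0.57, 1.90,  0.71)
  )
  col <- switch(group, total = 1:2, development = 3:4, validation = 5:6)
  out <- data.frame(
    variable = rownames(tab),
    mean = unname(tab[, col[1]]),
    sd = unname(tab[, col[2]]),
    lower = 0,
    stringsAsFactors = FALSE
  )
  out$lower[out$variable == "age"] <- 18
  rownames(out) <- NULL
  out
}

#' Reported female fraction of a study group
#'
#' @inheritParams study_marginals
#' @return Proportion of female subjects (121/212, 78/137 or 43/75).
#' @examples
#' study_sex_fraction("development")
#' @export
study_sex_fraction <- function(group = c("total", "development", "validation")) {
  switch(match.arg(group),
         total = 121 / 212, development = 78 / 137, validation = 43 / 75)
}

#' Reported pairwise Pearson correlations used for copula calibration
#'
#' The reported correlation coefficients between MVC strength, the twelve RMS
#' features (MeanRMS, MaxRMS, RatioRMS for EF/EE/KF/KE), segmental lean and
#' fat mass of the involved limb, ultrasound muscle thickness of the involved
#' muscle, and ASM. Comparisons pair each maneuver with its own body segment
#' (EF/EE with the dominant arm and biceps/triceps thickness; KF/KE with the
#' dominant leg and biceps femoris/rectus femoris thickness).
#'
#' @return A data.frame with columns `var_i`, `var_j`, `r`.
#' @seealso [study_assumed_correlations()], [correlation_target()]
#' @export
study_correlation_entries <- function() {
  e <- rbind(
    # MVC strength vs same-maneuver features and same-segment masses/thickness
    c("mvc_strength_EF", "mean_rms_EF",  0.671),
    c("mvc_strength_EF", "max_rms_EF",   0.679),
    c("mvc_strength_EF", "ratio_rms_EF", 0.412),
    c("mvc_strength_EF", "slm_arm",      0.747),
    c("mvc_strength_EF", "sfm_arm",     -0.279),
    c("mvc_strength_EF", "thickness_bb", 0.719),
    c("mvc_strength_EE", "mean_rms_EE",  0.531),
    c("mvc_strength_EE", "max_rms_EE",   0.288),
    c("mvc_strength_EE", "ratio_rms_EE", 0.400),
    c("mvc_strength_EE", "slm_arm",      0.778),
    c("mvc_strength_EE", "sfm_arm",     -0.258),
    c("mvc_strength_EE", "thickness_tb", 0.475),
    c("mvc_strength_KF", "mean_rms_KF",  0.529),
    c("mvc_strength_KF", "max_rms_KF",   0.505),
    c("mvc_strength_KF", "ratio_rms_KF", 0.266),
    c("mvc_strength_KF", "slm_leg",      0.618),
    c("mvc_strength_KF", "sfm_leg",     -0.177),
    c("mvc_strength_KF", "thickness_bf", 0.321),
    c("mvc_strength_KE", "mean_rms_KE",  0.506),
    c("mvc_strength_KE", "max_rms_KE",   0.480),
    c("mvc_strength_KE", "ratio_rms_KE", 0.390),
    c("mvc_strength_KE", "slm_leg",      0.595),
    c("mvc_strength_KE", "sfm_leg",     -0.195),
    c("mvc_strength_KE", "thickness_rf", 0.429),
    # RMS features vs same-segment masses, thickness and ASM
    c("mean_rms_EF",  "slm_arm",  0.432), c("mean_rms_EF",  "sfm_arm", -0.347),
    c("mean_rms_EF",  "thickness_bb", 0.457), c("mean_rms_EF",  "asm", 0.428),
    c("mean_rms_EE",  "slm_arm",  0.351), c("mean_rms_EE",  "sfm_arm", -0.392),
    c("mean_rms_EE",  "thickness_tb", 0.260), c("mean_rms_EE",  "asm", 0.377),
    c("mean_rms_KF",  "slm_leg",  0.270), c("mean_rms_KF",  "sfm_leg", -0.393),
    c("mean_rms_KF",  "thickness_bf", 0.151), c("mean_rms_KF",  "asm", 0.235),
    c("mean_rms_KE",  "slm_leg",  0.154), c("mean_rms_KE",  "sfm_leg", -0.162),
    c("mean_rms_KE",  "thickness_rf", 0.363), c("mean_rms_KE",  "asm", 0.136),
    c("max_rms_EF",   "slm_arm",  0.447), c("max_rms_EF",   "sfm_arm", -0.357),
    c("max_rms_EF",   "thickness_bb", 0.472), c("max_rms_EF",   "asm", 0.441),
    c("max_rms_EE",   "slm_arm",  0.158), c("max_rms_EE",   "sfm_arm", -0.211),
    c("max_rms_EE",   "thickness_tb", 0.213), c("max_rms_EE",   "asm", 0.170),
    c("max_rms_KF",   "slm_leg",  0.229), c("max_rms_KF",   "sfm_leg", -0.416),
    c("max_rms_KF",   "thickness_bf", 0.146), c("max_rms_KF",   "asm", 0.203),
    c("max_rms_KE",   "slm_leg",  0.129), c("max_rms_KE",   "sfm_leg", -0.166),
    c("max_rms_KE",   "thickness_rf", 0.375), c("max_rms_KE",   "asm", 0.114),
    c("ratio_rms_EF", "slm_arm",  0.341), c("ratio_rms_EF", "sfm_arm", -0.140),
    c("ratio_rms_EF", "thickness_bb", 0.297), c("ratio_rms_EF", "asm", 0.329),
    c("ratio_rms_EE", "slm_arm",  0.274), c("ratio_rms_EE", "sfm_arm", -0.249),
    c("ratio_rms_EE", "thickness_tb", 0.164), c("ratio_rms_EE", "asm", 0.297),
    c("ratio_rms_KF", "slm_leg",  0.366), c("ratio_rms_KF", "sfm_leg", -0.339),
    c("ratio_rms_KF", "thickness_bf", 0.264), c("ratio_rms_KF", "asm", 0.388),
    c("ratio_rms_KE", "slm_leg",  0.220), c("ratio_rms_KE", "sfm_leg", -0.133),
    c("ratio_rms_KE", "thickness_rf", 0.324), c("ratio_rms_KE", "asm", 0.218)
  )
  data.frame(var_i = e[, 1], var_j = e[, 2], r = as.numeric(e[, 3]),
             stringsAsFactors = FALSE)
}

#' Assumed correlations completing the copula calibration target
#'
#' The published tables pin down only part of the 30-variable correlation
#' matrix. Two groups of cells are filled with package assumptions before the
#' anchor-product rule takes over:
#' \itemize{
#'   \item anchor correlations with ASM for variables whose ASM correlation is
#'     not reported (covariates, masses, thickness, MVC strength). These follow
#'     standard body-composition physiology: ASM rises with height and weight,
#'     is lower in women and at older age, is essentially composed of the
#'     segmental lean masses, and relates moderately to muscle thickness and
#'     strength.
#'   \item within-maneuver feature correlations (MeanRMS-MaxRMS 0.95,
#'     MeanRMS-RatioRMS 0.50, MaxRMS-RatioRMS 0.45): the mean and the max
#'     summarise the same agonist electrodes and are necessarily strongly
#'     coupled; leaving these cells to the product fill would make them nearly
#'     independent and constantly produce physically infeasible electrode sets
#'     at rendering time.
#' }
#' The `sex` coordinate is the latent female propensity of the copula, so its
#' entries are latent-scale correlations.
#'
#' @return A data.frame with columns `var_i`, `var_j`, `r`.
#' @export
study_assumed_correlations <- function() {
  anchors <- c(age = -0.25, sex = -0.80, height = 0.85, weight = 0.72,
               bfm = -0.15, slm_arm = 0.93, slm_leg = 0.95,
               sfm_arm = -0.30, sfm_leg = -0.25,
               thickness_bb = 0.60, thickness_tb = 0.45,
               thickness_bf = 0.35, thickness_rf = 0.40,
               mvc_strength_EF = 0.75, mvc_strength_EE = 0.75,
               mvc_strength_KF = 0.60, mvc_strength_KE = 0.60)
  out <- data.frame(var_i = names(anchors), var_j = "asm",
                    r = unname(anchors), stringsAsFactors = FALSE)
  for (m in MANEUVERS) {
    out <- rbind(out, data.frame(
      var_i = c(paste0("mean_rms_", m), paste0("mean_rms_", m), paste0("max_rms_", m)),
      var_j = c(paste0("max_rms_", m), paste0("ratio_rms_", m), paste0("ratio_rms_", m)),
      r = c(0.95, 0.50, 0.45), stringsAsFactors = FALSE))
  }
  out
}

#' Names of the cohort variables entering the copula
#'
#' All numeric per-subject variables except BMI (recomputed from height and
#' weight, never sampled) plus the latent `sex` coordinate.
#' @return Character vector of variable names.
#' @export
cohort_variables <- function() {
  c("age", "sex", "height", "weight", "asm", "bfm",
    "slm_arm", "slm_leg", "sfm_arm", "sfm_leg",
    "thickness_bb", "thickness_tb", "thickness_bf", "thickness_rf",
    paste0("mvc_strength_", MANEUVERS),
    paste0("mean_rms_", MANEUVERS),
    paste0("max_rms_", MANEUVERS),
    paste0("ratio_rms_", MANEUVERS))
}
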