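#' Published ASM prediction equation coefficients
#'
#' The fixed-coefficient equation relating appendicular skeletal muscle mass
#' (kg) to height (m), weight (kg), sex (1 if female, 0 if male), the
#' knee-flexion co-contraction ratio RatioRMS(KF) and the elbow-extension
#' amplitude MeanRMS(EE) (mV):
#'
#' `ASM = -26.04 + 20.345*height + 0.178*weight - 2.065*female
#'        + 0.327*ratio_rms_KF + 0.965*mean_rms_EE`
#'
#' Reported fit statistics on the development group: SEE 1.167 kg,
#' R-squared 0.937, adjusted R-squared 0.934.
#'
#' @return Named numeric vector of the six coefficients (names match cohort
#'   columns; `female` is the sex indicator).
#' @examples
#' published_asm_equation()
#' @export
published_asm_equation <- function() {
  c("(Intercept)" = -26.04, height = 20.345, weight = 0.178,
    female = -2.065, ratio_rms_KF = 0.327, mean_rms_EE = 0.965)
}

#' Predict ASM from the published equation
#'
#' Pure fixed-coefficient arithmetic on the published values; deterministic
#' and platform-stable. Inputs outside the positive physical range are
#' rejected unless `permissive = TRUE` (useful for algebraic checks such as
#' reading off the intercept). Predictions are not floored at zero: the
#' equation is only validated over the study's covariate ranges, and
#' implausible inputs deliberately produce implausible outputs.
#'
#' @param height height in m.
#' @param weight weight in kg.
#' @param sex `"male"`/`"female"`, or a numeric female indicator (0 = male,
#'   1 = female; fractional values are accepted for group-mean evaluation).
#' @param ratio_rms_kf RatioRMS during knee flexion (dimensionless).
#' @param mean_rms_ee MeanRMS during elbow extension (mV).
#' @param permissive disable positivity bounds.
#' @return Predicted ASM in kg (vectorized over inputs).
#' @examples
#' predict_asm(1.75, 75, "male", 2.5, 0.8)
#' @export
predict_asm <- function(height, weight, sex, ratio_rms_kf, mean_rms_ee,
                        permissive = FALSE) {
  female <- sex_indicator(sex)
  if (!permissive &&
      (any(height <= 0) || any(weight <= 0) ||
       any(ratio_rms_kf <= 0) || any(mean_rms_ee <= 0)))
    stop("height, weight, ratio_rms_kf and mean_rms_ee must be > 0 ",
         "(use permissive = TRUE to disable bounds)")
  b <- published_asm_equation()
  b[["(Intercept)"]] + b[["height"]] * height + b[["weight"]] * weight +
    b[["female"]] * female + b[["ratio_rms_KF"]] * ratio_rms_kf +
    b[["mean_rms_EE"]] * mean_rms_ee
}

sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(sex)
  if (is.factor(sex)) sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("unknown sex category: ",
         paste(unique(setdiff(sex, c("male", "female"))), collapse = ", "))
  as.numeric(sex == "female")
}

#' Predict ASM for every row of a cohort table
#'
#' @param cohort cohort data.frame with columns `height`, `weight`, `sex`,
#'   `ratio_rms_KF`, `mean_rms_EE`.
#' @return The cohort with columns `predicted_asm`, `asm_over_height2` and
#'   `low_muscle_mass` (flag computed from the prediction) appended.
#' @export
predict_asm_cohort <- function(cohort) {
  pred <- predict_asm(cohort$height, cohort$weight, cohort$sex,
                      cohort$ratio_rms_KF, cohort$mean_rms_EE)
  cohort$predicted_asm <- pred
  cohort$asm_over_height2 <- pred / cohort$height^2
  cohort$low_muscle_mass <- low_muscle_mass(pred, cohort$height, cohort$sex)
  cohort
}

#' Low-muscle-mass screening flag
#'
#' TRUE when the skeletal muscle index ASM/height^2 falls strictly below the
#' sex-specific screening cutoff: 7.0 kg/m^2 for men, 5.7 kg/m^2 for women.
#'
#' @param asm appendicular skeletal muscle mass in kg.
#' @param height height in m, > 0.
#' @param sex `"male"`/`"female"` (or numeric female indicator 0/1).
#' @return Logical vector.
#' @examples
#' low_muscle_mass(20, 1.70, "male") # 6.92 < 7.0
#' @export
low_muscle_mass <- function(asm, height, sex) {
  if (any(height <= 0)) stop("height must be > 0")
  female <- sex_indicator(sex)
  if (!all(female %in% c(0, 1)))
    stop("sex must resolve to a 0/1 indicator for classification")
  cutoff <- ifelse(female == 1, 5.7, 7.0)
  asm / height^2 < cutoff
}

#' Body mass index
#'
#' @param weight weight in kg.
#' @param height height in m, > 0.
#' @return `weight / height^2` in kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(height <= 0)) stop("height must be > 0")
  weight / height^2
}
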