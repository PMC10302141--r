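cohort_columns <- function() {
  c("subject_id", "age", "sex", "height", "weight", "bmi", "asm", "bfm",
    "slm_arm", "slm_leg", "sfm_arm", "sfm_leg",
    "thickness_bb", "thickness_tb", "thickness_bf", "thickness_rf",
    as.vector(t(outer(c("mvc_strength_", "mean_rms_", "max_rms_", "ratio_rms_"),
                      MANEUVERS, paste0))),
    "group_label")
}

empty_cohort <- function() {
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cohort_columns())),
                                cohort_columns()))
  out$subject_id <- character(0)
  out$sex <- character(0)
  out$group_label <- character(0)
  out
}

#' Sample a synthetic study cohort through a Gaussian copula
#'
#' Draws a latent multivariate standard normal vector per subject with the
#' supplied correlation matrix and maps each continuous coordinate through the
#' quantile function of a moment-matched truncated normal: the parent normal's
#' parameters are solved so that, after truncation at the variable's physical
#' floor, the marginal mean and SD equal the specified values exactly. This
#' respects the floors without the upward bias that row-wise rejection
#' sampling would leak into every correlated variable. Sex is obtained by
#' thresholding the latent `sex` coordinate at the quantile matching the
#' requested female fraction, so sex-variable correlations are representable
#' on the latent scale. BMI is recomputed from the sampled height and weight,
#' never sampled itself. The draw is fully deterministic given `seed`.
#'
#' @param n number of subjects (`n = 0` yields an empty table with full schema).
#' @param marginals data.frame with columns `variable`, `mean`, `sd`, `lower`
#'   covering every continuous copula variable (see [study_marginals()]).
#' @param corr a [correlation_target()] result or a plain named correlation
#'   matrix over `c(marginals$variable, "sex")`.
#' @param sex_fraction_female proportion of female subjects targeted.
#' @param seed integer master seed.
#' @return A cohort data.frame, one row per subject, with `group_label`
#'   `"unassigned"`.
#' @examples
#' coh <- sample_cohort(20, seed = 1)
#' mean(coh$sex == "female")
#' @export
sample_cohort <- function(n,
                          marginals = study_marginals("total"),
                          corr = study_correlation_target(),
                          sex_fraction_female = study_sex_fraction("total"),
                          seed = 1) {
  stopifnot(n >= 0, sex_fraction_female >= 0, sex_fraction_female <= 1)
  R <- if (inherits(corr, "corr_target")) corr$matrix else corr
  stopifnot(is.matrix(R), !is.null(dimnames(R)))
  marginals <- as.data.frame(marginals)
  if (any(marginals$sd < 0)) stop("marginal sd must be >= 0")
  if (any(marginals$lower >= marginals$mean))
    stop("marginal lower bound must lie below the mean")
  vars <- colnames(R)
  need <- c(marginals$variable, "sex")
  if (!setequal(vars, need))
    stop("correlation matrix variables do not match marginals (+ sex): missing ",
         paste(setdiff(need, vars), collapse = ", "), "; extra ",
         paste(setdiff(vars, need), collapse = ", "))
  if (n == 0) return(empty_cohort())

  set.seed(child_seed(seed, "cohort"))
  Z <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R, tol = 1e-6)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- colnames(R)
  cont <- marginals$variable
  X <- vapply(seq_along(cont), function(j) {
    truncnorm_transform(Z[, cont[j]], marginals$mean[j], marginals$sd[j],
                        marginals$lower[j])
  }, numeric(n))
  if (n == 1) X <- matrix(X, nrow = 1)
  colnames(X) <- cont

  female <- Z[, "sex"] > qnorm(1 - sex_fraction_female)
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    as.data.frame(X), stringsAsFactors = FALSE)
  out$sex <- ifelse(female, "female", "male")
  out$bmi <- out$weight / out$height^2
  out$group_label <- "unassigned"
  out[, cohort_columns()]
}

# Parameters (mu, sigma) of a parent normal whose truncation at `lower`
# has mean m and standard deviation s. With a = (lower - mu)/sigma and
# hazard lambda(a) = phi(a)/(1 - Phi(a)):
#   E[X] - lower = sigma * (lambda - a),  Var[X] = sigma^2 * (1 + a*lambda - lambda^2)
# so a solves (lambda - a)/sqrt(1 + a*lambda - lambda^2) = (m - lower)/s.
solve_truncnorm <- function(m, s, lower) {
  delta <- (m - lower) / s
  rho <- function(a) {
    lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
    (lam - a) / sqrt(pmax(1 + a * lam - lam^2, 1e-12))
  }
  a <- uniroot(function(a) rho(a) - delta, c(-40, 8), tol = 1e-12)$root
  lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
  sigma <- s / sqrt(1 + a * lam - lam^2)
  list(mu = lower - sigma * a, sigma = sigma, alpha = a)
}

# map standard-normal latents to the moment-matched truncated normal via the
# copula quantile transform
truncnorm_transform <- function(z, m, s, lower) {
  p <- solve_truncnorm(m, s, lower)
  pa <- pnorm(p$alpha)
  u <- pmin(pmax(pnorm(z), 1e-15), 1 - 1e-15)
  p$mu + p$sigma * qnorm(pa + u * (1 - pa))
}

check_cohort <- function(cohort, require_consistent_max = FALSE) {
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  num <- setdiff(cohort_columns(), c("subject_id", "sex", "group_label", "age"))
  if (nrow(cohort)) {
    if (any(as.matrix(cohort[num]) <= 0))
      stop("cohort masses, thicknesses, strengths and RMS values must be > 0")
    if (max(abs(cohort$bmi - cohort$weight / cohort$height^2)) > 1e-9)
      stop("bmi column inconsistent with weight/height^2")
    if (!all(cohort$sex %in% c("male", "female")))
      stop("sex must be 'male' or 'female'")
    if (require_consistent_max) {
      for (m in MANEUVERS)
        if (any(cohort[[paste0("max_rms_", m)]] < cohort[[paste0("mean_rms_", m)]]))
          stop("max_rms_", m, " below mean_rms_", m)
    }
  }
  invisible(cohort)
}
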