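#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value on `n - 2`
#' degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant.
#' @param var_i,var_j optional variable labels carried into the result.
#' @return Data.frame row: `var_i`, `var_j`, `r`, `p_value`, `n`.
#' @examples
#' pearson(1:10, (1:10) * 2 + 1)$r
#' @export
pearson <- function(x, y, var_i = "x", var_j = "y") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(var_i = var_i, var_j = var_j, r = unname(ct$estimate),
             p_value = ct$p.value, n = length(x), stringsAsFactors = FALSE)
}

#' Default variable pairing mirroring the published correlation tables
#'
#' Pairs each maneuver's MVC strength and RMS features with the same-maneuver
#' features and the involved body segment's lean mass, fat mass and muscle
#' thickness, plus each RMS feature with ASM.
#'
#' @return Data.frame with columns `var_i`, `var_j`.
#' @export
study_pairing <- function() {
  e <- study_correlation_entries()
  e[c("var_i", "var_j")]
}

#' Correlation table over cohort variables
#'
#' @param cohort cohort data.frame.
#' @param pairing data.frame with columns `var_i`, `var_j`;
#'   default [study_pairing()].
#' @return Data.frame of [pearson()] rows, one per pair.
#' @export
correlation_table <- function(cohort, pairing = study_pairing()) {
  pairing <- as.data.frame(pairing)
  if (!nrow(pairing))
    return(data.frame(var_i = character(0), var_j = character(0),
                      r = numeric(0), p_value = numeric(0), n = integer(0)))
  miss <- setdiff(unique(c(pairing$var_i, pairing$var_j)), names(cohort))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(pairing)), function(k) {
    pearson(cohort[[pairing$var_i[k]]], cohort[[pairing$var_j[k]]],
            pairing$var_i[k], pairing$var_j[k])
  }))
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j` on
#' all other predictors with intercept. Perfectly collinear predictors are
#' reported as `Inf` and flagged via the `collinear` attribute.
#'
#' @param predictors data.frame or matrix of >= 2 non-constant numeric columns.
#' @return Named numeric vector of VIFs (attribute `collinear`: logical).
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("VIF requires at least 2 predictors")
  if (any(vapply(X, sd, numeric(1)) == 0)) stop("constant predictor")
  out <- vapply(names(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[setdiff(names(X), j)])
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fits flagged below
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(out, "collinear") <- !is.finite(out)
  out
}

#' Durbin-Watson statistic of ordered residuals
#'
#' `sum(diff(e)^2) / sum(e^2)`; close to 2 under no serial correlation. On
#' cross-sectional cohorts the value depends on row order, which is therefore
#' part of the analysis record.
#'
#' @param residuals numeric vector, length >= 2, not all zero.
#' @return The statistic (in `(0, 4)` for non-degenerate input).
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  if (all(residuals == 0)) stop("all residuals are zero")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Stepwise ordinary least squares with p-value entry/removal
#'
#' Forward selection with backward elimination in the classic SPSS style: at
#' each step the candidate with the smallest partial-F p-value enters if below
#' `p_enter`, then any included term with p above `p_remove` is dropped
#' (worst first). The procedure stops when no move is possible or a visited
#' model recurs. The final model is refit by OLS with intercept and reported
#' with SEE, R-squared, adjusted R-squared, Durbin-Watson statistic and VIFs.
#'
#' @param data data.frame holding response and candidates.
#' @param response response column name.
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter,p_exit entry/removal thresholds (defaults 0.05 / 0.10;
#'   requires `p_enter <= p_exit`).
#' @return Object of class `stepwise_ols`: list with `fit` (the `lm`),
#'   `terms` (data.frame: term, beta, se, p_value), `see`, `r2`, `adj_r2`,
#'   `dw`, `vif`, `n`, `response`, `selected`, `steps` (log of moves).
#' @examples
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), z = rnorm(100))
#' d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(100, sd = 0.3)
#' stepwise_ols(d, "y", c("x1", "x2", "z"))
#' @export
stepwise_ols <- function(data, response, candidates,
                         p_enter = 0.05, p_exit = 0.10) {
  stopifnot(p_enter <= p_exit)
  data <- as.data.frame(data)
  miss <- setdiff(c(response, candidates), names(data))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n <= length(candidates) + 1)
    stop("need n > number of candidates + 1 (n = ", n, ")")

  included <- character(0)
  visited <- character(0)
  steps <- character(0)
  base_formula <- function(terms) {
    as.formula(paste(response, "~",
                     if (length(terms)) paste(terms, collapse = " + ") else "1"))
  }
  # F tests are meaningless once the fit is numerically perfect
  is_perfect <- function(fit) {
    y <- fit$model[[1]]
    sum(resid(fit)^2) <= 1e-12 * sum((y - mean(y))^2)
  }
  repeat {
    sig <- paste(sort(included), collapse = "+")
    if (sig %in% visited) { steps <- c(steps, "cycle detected; stop"); break }
    visited <- c(visited, sig)
    fit <- lm(base_formula(included), data = data)
    if (is_perfect(fit)) { steps <- c(steps, "perfect fit; stop"); break }
    moved <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      a1 <- add1(fit, scope = base_formula(union(included, pool)), test = "F")
      pv <- a1[["Pr(>F)"]]; names(pv) <- rownames(a1)
      pv <- pv[pool]
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        best <- names(which.min(pv))
        included <- c(included, best)
        steps <- c(steps, paste("enter", best))
        fit <- lm(base_formula(included), data = data)
        moved <- TRUE
      }
    }
    if (length(included) && !is_perfect(fit)) {
      d1 <- drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]]; names(pv) <- rownames(d1)
      pv <- pv[included]
      while (length(pv) && max(pv, na.rm = TRUE) > p_exit) {
        worst <- names(which.max(pv))
        included <- setdiff(included, worst)
        steps <- c(steps, paste("remove", worst))
        moved <- TRUE
        fit <- lm(base_formula(included), data = data)
        if (!length(included)) break
        d1 <- drop1(fit, test = "F")
        pv <- d1[["Pr(>F)"]]; names(pv) <- rownames(d1)
        pv <- pv[included]
      }
    }
    if (!moved) break
  }

  fit <- lm(base_formula(included), data = data)
  if (length(included) >= 2) {
    kap <- kappa(qr.R(fit$qr), exact = TRUE)
    if (kap > 1e10)
      stop("collinear candidates survived to the final fit (condition number ",
           format(kap, digits = 3), ")")
  }
  sm <- suppressWarnings(summary(fit)) # perfect fits are legitimate results
  k <- length(included)
  rss <- sum(resid(fit)^2)
  terms_tab <- data.frame(
    term = rownames(sm$coefficients),
    beta = unname(sm$coefficients[, 1]),
    se = unname(sm$coefficients[, 2]),
    p_value = unname(sm$coefficients[, 4]),
    stringsAsFactors = FALSE
  )
  structure(list(
    fit = fit,
    terms = terms_tab,
    selected = included,
    see = sqrt(rss / (n - k - 1)),
    r2 = sm$r.squared,
    adj_r2 = 1 - (1 - sm$r.squared) * (n - 1) / (n - k - 1),
    dw = durbin_watson(resid(fit)),
    vif = if (k >= 2) vif(data[included]) else setNames(rep(1, k), included),
    n = n,
    response = response,
    p_enter = p_enter,
    p_exit = p_exit,
    steps = steps
  ), class = "stepwise_ols")
}

#' @export
print.stepwise_ols <- function(x, digits = 4, ...) {
  cat("Stepwise OLS:", x$response, "~",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "1",
      sprintf(" (n = %d)\n", x$n))
  tab <- x$terms
  tab$vif <- c(NA, unname(x$vif))[seq_len(nrow(tab))]
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f, SEE = %.3f, Durbin-Watson = %.3f\n",
              x$r2, x$adj_r2, x$see, x$dw))
  invisible(x)
}

#' Randomly split a cohort into development and validation groups
#'
#' Uniform partition without replacement, deterministic per seed; sets
#' `group_label` on both returned tables.
#'
#' @param cohort cohort data.frame.
#' @param n_development development-group size (study protocol: 137 of 212).
#' @param seed integer seed.
#' @return List with `development` and `validation` data.frames.
#' @export
split_cohort <- function(cohort, n_development = 137, seed = 1) {
  n <- nrow(cohort)
  if (n_development >= n)
    stop("n_development must be smaller than the cohort size")
  if (n_development < 1) stop("n_development must be >= 1")
  set.seed(child_seed(seed, "split"))
  idx <- sort(sample.int(n, n_development))
  dev <- cohort[idx, , drop = FALSE]
  val <- cohort[-idx, , drop = FALSE]
  dev$group_label <- "development"
  val$group_label <- "validation"
  rownames(dev) <- rownames(val) <- NULL
  list(development = dev, validation = val)
}

#' Cross-validate an ASM model on a held-out group
#'
#' Applies the model's coefficients to the validation table and compares
#' predicted against measured response with Pearson correlation and a paired
#' two-sided t-test.
#'
#' @param model a [stepwise_ols()] fit, or a named coefficient vector with an
#'   `(Intercept)` entry (e.g. from [published_asm_equation()], after renaming
#'   to cohort columns).
#' @param validation cohort data.frame containing all model terms.
#' @param response measured response column, default `"asm"`.
#' @return Object of class `validation_report`: list with
#'   `r_pred_vs_measured`, `r_p_value`, `paired_t_p`, `mean_predicted`,
#'   `mean_measured`, `n`, `predicted`.
#' @export
cross_validate <- function(model, validation, response = "asm") {
  if (inherits(model, "stepwise_ols")) {
    beta <- setNames(model$terms$beta, model$terms$term)
  } else {
    beta <- model
  }
  terms <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(terms, names(validation))
  if (length(miss)) stop("validation table lacks term(s): ",
                         paste(miss, collapse = ", "))
  if (!response %in% names(validation)) stop("missing response: ", response)
  X <- as.matrix(validation[terms])
  pred <- as.numeric(X %*% beta[terms]) +
    if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  meas <- validation[[response]]
  pr <- pearson(pred, meas, "predicted", response)
  d <- pred - meas
  paired_p <- if (sd(d) <= 1e-12 * max(abs(d), 1)) {
    # degenerate case: all differences identical (e.g. noiseless round trip)
    if (abs(mean(d)) <= 1e-12) 1 else 0
  } else t.test(pred, meas, paired = TRUE)$p.value
  structure(list(r_pred_vs_measured = pr$r, r_p_value = pr$p_value,
                 paired_t_p = paired_p,
                 mean_predicted = mean(pred), mean_measured = mean(meas),
                 n = length(meas), predicted = pred),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Cross-validation (n = %d): r = %.3f, paired-t p = %.3g\n  predicted %.2f vs measured %.2f kg\n",
    x$n, x$r_pred_vs_measured, x$paired_t_p, x$mean_predicted, x$mean_measured))
  invisible(x)
}
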