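test_that("pearson matches the covariance formula and handles exact fits", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  # hand-computed: centered cross-products 3, variances 5 and 5 -> r = 3/5
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
  out <- pearson(rnorm(20), rnorm(20), "a", "b")
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_equal(out$n, 20)
})

test_that("correlation_table mirrors the maneuver/segment pairing", {
  coh <- calibration_cohort()
  tab <- correlation_table(coh)
  expect_equal(nrow(tab), nrow(study_pairing()))
  r_mvc_slm <- tab$r[tab$var_i == "mvc_strength_EF" & tab$var_j == "slm_arm"]
  expect_equal(r_mvc_slm, 0.747, tolerance = 0.03)
  expect_equal(correlation_table(coh,
                                 data.frame(var_i = character(0),
                                            var_j = character(0))) |> nrow(), 0)
  expect_error(correlation_table(coh, data.frame(var_i = "nope",
                                                 var_j = "asm")), "unknown")
})

test_that("independent columns correlate near zero", {
  d <- noise_design(10000, 4, seed = 50)
  tab <- correlation_table(d, data.frame(var_i = c("x1", "x1", "x2"),
                                         var_j = c("x2", "x3", "x4")))
  expect_true(all(abs(tab$r) < 0.05))
})

test_that("VIF matches its definitional oracle and flags collinearity", {
  d <- data.frame(a = rep(c(1, -1), 25), b = rep(c(1, 1, -1, -1), length.out = 50))
  expect_equal(unname(vif(d)), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(51)
  x1 <- rnorm(10000)
  d2 <- data.frame(x1 = x1, x2 = x1 + rnorm(10000, sd = 0.6), x3 = rnorm(10000))
  v <- vif(d2)
  r2 <- summary(lm(x2 ~ x1 + x3, data = d2))$r.squared
  expect_equal(v[["x2"]], 1 / (1 - r2), tolerance = 1e-9)
  d3 <- data.frame(x1 = x1[1:50], x2 = x1[1:50])
  v3 <- suppressWarnings(vif(d3))
  expect_true(all(is.infinite(v3)))
  expect_true(all(attr(v3, "collinear")))
})

test_that("VIF agrees with the car oracle on a fitted model", {
  skip_if_not_installed("car")
  set.seed(52)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$x3 <- d$x1 * 0.5 + rnorm(200)
  d$y <- d$x1 + d$x2 + rnorm(200)
  fit <- lm(y ~ x1 + x2 + x3, data = d)
  expect_equal(unname(vif(d[c("x1", "x2", "x3")])),
               unname(car::vif(fit)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Durbin-Watson matches closed forms and the lmtest oracle", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  expect_error(durbin_watson(rep(0, 10)), "zero")
  set.seed(53)
  e <- rnorm(100000)
  expect_equal(durbin_watson(e), 2, tolerance = 0.02)
  skip_if_not_installed("lmtest")
  d <- data.frame(x = rnorm(80))
  d$y <- d$x + rnorm(80)
  fit <- lm(y ~ x, data = d)
  expect_equal(durbin_watson(resid(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-9)
})

test_that("stepwise keeps an exact predictor and drops pure noise", {
  d <- noise_design(200, 6, seed = 54)
  d$y <- 2 * d$x1 + 5 # exact linear relation, no noise
  fit <- stepwise_ols(d, "y", paste0("x", 1:6))
  expect_equal(fit$selected, "x1")
  expect_equal(unname(coef(fit$fit)), c(5, 2), tolerance = 1e-9)
})

test_that("stepwise recovers a planted two-term model", {
  d <- noise_design(1000, 8, seed = 55)
  set.seed(56)
  d$y <- 3 + 2 * d$x1 - 1 * d$x2 + rnorm(1000, sd = 0.5)
  fit <- stepwise_ols(d, "y", paste0("x", 1:8))
  expect_true(all(c("x1", "x2") %in% fit$selected))
  tt <- fit$terms
  truth <- c("(Intercept)" = 3, x1 = 2, x2 = -1)
  for (nm in names(truth)) {
    row <- tt[tt$term == nm, ]
    expect_lt(abs(row$beta - truth[[nm]]) / row$se, 3)
  }
})

test_that("null-candidate selection matches the order-statistic oracle", {
  k <- 5
  n_rep <- 60
  hits <- vapply(seq_len(n_rep), function(r) {
    d <- noise_design(300, k, seed = 5000 + r)
    set.seed(6000 + r)
    d$y <- rnorm(300)
    length(stepwise_ols(d, "y", paste0("x", 1:k))$selected) == 0
  }, logical(1))
  # P(intercept-only) = P(min of k null p-values >= 0.05) ~= 0.95^k
  p0 <- 0.95^k
  expect_gt(mean(hits), p0 - 4 * sqrt(p0 * (1 - p0) / n_rep))
  expect_lt(mean(hits), p0 + 4 * sqrt(p0 * (1 - p0) / n_rep))
})

test_that("every included term is significant and no excluded term would enter", {
  coh <- sample_cohort(400, seed = 57)
  coh$female <- as.numeric(coh$sex == "female")
  pool <- c("age", "female", "height", "weight",
            paste0("mean_rms_", c("EF", "EE", "KF", "KE")))
  fit <- stepwise_ols(coh, "asm", pool)
  d1 <- drop1(fit$fit, test = "F")
  pin <- d1[["Pr(>F)"]][match(fit$selected, rownames(d1))]
  expect_true(all(pin < fit$p_exit))
  out <- setdiff(pool, fit$selected)
  if (length(out)) {
    a1 <- add1(fit$fit, scope = as.formula(
      paste("asm ~", paste(c(fit$selected, out), collapse = "+"))), test = "F")
    pout <- a1[["Pr(>F)"]][match(out, rownames(a1))]
    expect_true(all(pout >= fit$p_enter))
  }
})

test_that("fit statistics match their definitional oracles", {
  coh <- sample_cohort(150, seed = 58)
  coh$female <- as.numeric(coh$sex == "female")
  fit <- stepwise_ols(coh, "asm", c("height", "weight", "female", "age"))
  lmfit <- fit$fit
  n <- fit$n
  k <- length(fit$selected)
  rss <- sum(resid(lmfit)^2)
  expect_equal(fit$see, sqrt(rss / (n - k - 1)), tolerance = 1e-9)
  expect_equal(fit$r2, summary(lmfit)$r.squared, tolerance = 1e-12)
  expect_equal(fit$adj_r2,
               1 - (1 - fit$r2) * (n - 1) / (n - k - 1), tolerance = 1e-9)
  expect_equal(fit$adj_r2, summary(lmfit)$adj.r.squared, tolerance = 1e-9)
  expect_lte(fit$adj_r2, fit$r2)
  expect_true(all(fit$vif >= 1))
  # OLS with intercept passes through the mean point
  means <- vapply(coh[fit$selected], mean, numeric(1))
  pred_at_mean <- sum(coef(lmfit) * c(1, means))
  expect_equal(pred_at_mean, mean(coh$asm), tolerance = 1e-9)
})

test_that("stepwise input validation works", {
  d <- noise_design(8, 8, seed = 59)
  d$y <- rnorm(8)
  expect_error(stepwise_ols(d, "y", paste0("x", 1:8)), "n >")
  expect_error(stepwise_ols(d, "z", "x1"), "unknown column")
  expect_error(stepwise_ols(d, "y", "x1", p_enter = 0.2, p_exit = 0.1))
})

test_that("the cohort split reproduces the study partition logic", {
  coh <- sample_cohort(212, seed = 60)
  sp <- split_cohort(coh, 137, seed = 60)
  expect_equal(nrow(sp$development), 137)
  expect_equal(nrow(sp$validation), 75)
  expect_equal(sort(c(sp$development$subject_id, sp$validation$subject_id)),
               sort(coh$subject_id))
  expect_length(intersect(sp$development$subject_id,
                          sp$validation$subject_id), 0)
  expect_true(all(sp$development$group_label == "development"))
  expect_true(all(sp$validation$group_label == "validation"))
  sp2 <- split_cohort(coh, 137, seed = 60)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(coh, 211, seed = 1)
  expect_equal(nrow(sp3$validation), 1)
  expect_error(split_cohort(coh, 212, seed = 1), "smaller")
})

test_that("cross-validation recovers exact and shifted predictions", {
  coh <- sample_cohort(100, seed = 61)
  coh$female <- as.numeric(coh$sex == "female")
  b <- published_asm_equation()
  coh$asm <- b[["(Intercept)"]] + b[["height"]] * coh$height +
    b[["weight"]] * coh$weight + b[["female"]] * coh$female +
    b[["ratio_rms_KF"]] * coh$ratio_rms_KF + b[["mean_rms_EE"]] * coh$mean_rms_EE
  rep0 <- cross_validate(b, coh)
  expect_equal(rep0$r_pred_vs_measured, 1, tolerance = 1e-9)
  expect_equal(rep0$mean_predicted, rep0$mean_measured, tolerance = 1e-9)
  # a constant shift keeps r = 1 but fails the paired t-test
  b2 <- b
  b2[["(Intercept)"]] <- b2[["(Intercept)"]] + 0.5
  rep1 <- cross_validate(b2, coh)
  expect_equal(rep1$r_pred_vs_measured, 1, tolerance = 1e-9)
  expect_lt(rep1$paired_t_p, 1e-6)
  expect_error(cross_validate(c("(Intercept)" = 0, nothere = 1), coh),
               "lacks term")
})

test_that("study-scale synthetic runs cross-validate strongly", {
  rs <- vapply(1:10, function(s) {
    coh <- sample_cohort(212, seed = 700 + s)
    coh$female <- as.numeric(coh$sex == "female")
    sp <- split_cohort(coh, 137, seed = s)
    mans <- c("EF", "EE", "KF", "KE")
    pool <- c("age", "female", "height", "weight",
              paste0("mean_rms_", mans), paste0("max_rms_", mans),
              paste0("ratio_rms_", mans))
    fit <- stepwise_ols(sp$development, "asm", pool)
    cross_validate(fit, sp$validation)$r_pred_vs_measured
  }, numeric(1))
  expect_gt(median(rs), 0.85)
  expect_true(all(rs > 0.75))
})
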