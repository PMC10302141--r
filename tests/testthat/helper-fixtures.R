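# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# large calibrated cohort used by the calibration and acceptance checks
calibration_cohort <- function(n = 50000, seed = 101) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- sample_cohort(n, seed = seed)
  .fixture_env[[key]]
}

# cohort whose ASM is generated exactly by the published equation plus noise
equation_cohort <- function(n, noise_sd = 1.167, seed = 7) {
  coh <- sample_cohort(n, seed = seed)
  coh$female <- as.numeric(coh$sex == "female")
  b <- published_asm_equation()
  set.seed(child_seed(seed, "equation-noise"))
  coh$asm <- b[["(Intercept)"]] + b[["height"]] * coh$height +
    b[["weight"]] * coh$weight + b[["female"]] * coh$female +
    b[["ratio_rms_KF"]] * coh$ratio_rms_KF +
    b[["mean_rms_EE"]] * coh$mean_rms_EE + rnorm(n, sd = noise_sd)
  coh
}

# independent eigenvalue-clipping oracle for the PSD repair
clip_oracle <- function(R, iters = 100) {
  for (i in seq_len(iters)) {
    e <- eigen(R, symmetric = TRUE)
    R <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
  }
  R
}

# small synthetic regression design with independent standard-normal columns
noise_design <- function(n, k, seed) {
  set.seed(seed)
  as.data.frame(setNames(lapply(seq_len(k), function(i) rnorm(n)),
                         paste0("x", seq_len(k))))
}
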