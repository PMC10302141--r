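test_that("a valid correlation matrix is a fixed point of assembly and repair", {
  printed <- data.frame(var_i = c("a", "a", "b"),
                        var_j = c("b", "c", "c"),
                        r = c(0.5, 0.3, 0.2))
  ct <- correlation_target(printed, fill_rule = "zero",
                           variables = c("a", "b", "c"))
  expect_equal(ct$matrix,
               matrix(c(1, 0.5, 0.3, 0.5, 1, 0.2, 0.3, 0.2, 1), 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  expect_equal(ct$printed_deviation, 0)
  expect_true(all(ct$provenance[upper.tri(ct$provenance)] == "printed"))
})

test_that("empty printed set with zero fill yields the identity", {
  ct <- correlation_target(data.frame(var_i = character(0),
                                      var_j = character(0), r = numeric(0)),
                           fill_rule = "zero", variables = letters[1:4])
  expect_equal(unname(ct$matrix), diag(4))
})

test_that("non-PSD input is repaired to the clipping oracle's fixed point", {
  printed <- data.frame(var_i = c("a", "a", "b"),
                        var_j = c("b", "c", "c"),
                        r = c(0.99, 0.99, -0.99))
  ct <- correlation_target(printed, fill_rule = "zero",
                           variables = c("a", "b", "c"))
  raw <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3)
  expect_equal(unname(ct$matrix), clip_oracle(raw), tolerance = 1e-7)
  ev <- eigen(ct$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8)
  expect_true(all(abs(ct$matrix) <= 1 + 1e-12))
  expect_true(any(ct$provenance == "repaired"))
})

test_that("anchor-product fill places products through the anchor", {
  printed <- data.frame(var_i = c("x", "y"), var_j = c("asm", "asm"),
                        r = c(0.8, 0.5))
  ct <- correlation_target(printed, fill_rule = "anchor_product",
                           variables = c("x", "y", "asm"))
  expect_equal(ct$matrix["x", "y"], 0.8 * 0.5, tolerance = 1e-9)
})

test_that("conflicting duplicates and out-of-range entries are rejected", {
  expect_error(correlation_target(
    data.frame(var_i = c("a", "b"), var_j = c("b", "a"), r = c(0.5, 0.6)),
    variables = c("a", "b")), "conflicting duplicate")
  expect_error(correlation_target(
    data.frame(var_i = "a", var_j = "b", r = 1.2), variables = c("a", "b")),
    "<= 1")
  # exact duplicates are tolerated
  expect_silent(correlation_target(
    data.frame(var_i = c("a", "b"), var_j = c("b", "a"), r = c(0.5, 0.5)),
    fill_rule = "zero", variables = c("a", "b")))
})

test_that("the study target is near-PSD before repair and repair is idempotent", {
  ct <- study_correlation_target()
  expect_equal(diag(ct$matrix), setNames(rep(1, 30), cohort_variables()))
  expect_lt(ct$printed_deviation, 0.005)
  again <- repair_correlation(ct$matrix)
  expect_lt(max(abs(again$matrix - ct$matrix)), 1e-8)
  ev <- eigen(ct$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("repair agrees with the nearest-correlation solver on printed cells", {
  skip_if_not_installed("Matrix")
  printed <- study_correlation_entries()
  ct <- study_correlation_target()
  # assemble the raw (pre-repair) matrix independently and run Higham's method
  raw <- outer(rep(0, 30), rep(0, 30))
  dimnames(raw) <- list(cohort_variables(), cohort_variables())
  assumed <- study_assumed_correlations()
  a <- setNames(rep(0, 30), cohort_variables()); a["asm"] <- 1
  for (k in seq_len(nrow(assumed)))
    if (assumed$var_j[k] == "asm") a[assumed$var_i[k]] <- assumed$r[k]
  for (k in seq_len(nrow(printed)))
    if (printed$var_j[k] == "asm") a[printed$var_i[k]] <- printed$r[k]
  raw <- outer(a, a); diag(raw) <- 1
  for (k in seq_len(nrow(assumed))) {
    raw[assumed$var_i[k], assumed$var_j[k]] <-
      raw[assumed$var_j[k], assumed$var_i[k]] <- assumed$r[k]
  }
  for (k in seq_len(nrow(printed))) {
    raw[printed$var_i[k], printed$var_j[k]] <-
      raw[printed$var_j[k], printed$var_i[k]] <- printed$r[k]
  }
  higham <- as.matrix(Matrix::nearPD(raw, corr = TRUE)$mat)
  for (k in seq_len(nrow(printed)))
    expect_equal(ct$matrix[printed$var_i[k], printed$var_j[k]],
                 higham[printed$var_i[k], printed$var_j[k]], tolerance = 0.01)
})
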