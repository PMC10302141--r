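fs <- 4096
one_sec <- seq(0, 1 - 1 / fs, by = 1 / fs)
full_window <- analysis_window(0, 1)

test_that("a mid-band tone passes with unit gain", {
  x <- sin(2 * pi * 300 * one_sec)
  y <- bandpass_filter(x, fs)
  # interior window avoids edge transients; tone RMS is amplitude / sqrt(2)
  rms <- compute_rms(y, fs, analysis_window(0.1, 0.9))
  expect_gt(rms, 0.99 / sqrt(2))
  expect_lt(rms, 1.01 / sqrt(2))
})

test_that("DC and out-of-band tones are strongly attenuated", {
  dc <- rep(1, fs)
  expect_lt(compute_rms(bandpass_filter(dc, fs), fs,
                        analysis_window(0.1, 0.9)), 0.01)
  for (f0 in c(50, 1000)) { # one octave outside each band edge
    x <- sin(2 * pi * f0 * one_sec)
    y <- bandpass_filter(x, fs)
    atten <- compute_rms(y, fs, analysis_window(0.25, 0.75)) / (1 / sqrt(2))
    expect_lt(20 * log10(atten), -40)
  }
})

test_that("the zero trace maps to the zero trace", {
  expect_equal(bandpass_filter(rep(0, fs), fs), rep(0, fs))
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(5)
  x <- rnorm(2 * fs)
  a <- bandpass_filter(x, fs)
  b <- rev(bandpass_filter(rev(x), fs))
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("filter preconditions are enforced", {
  expect_error(bandpass_filter(rnorm(fs), fs, filter_spec(100, 2048)),
               "Nyquist")
  expect_error(bandpass_filter(rnorm(50), fs), "too short")
  expect_error(filter_spec(500, 100), NULL)
})

test_that("rectification is the absolute value and preserves RMS", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(rep(0, 5)), rep(0, 5))
  set.seed(2)
  x <- rnorm(1000)
  expect_equal(sqrt(mean(rectify(x)^2)), sqrt(mean(x^2)), tolerance = 1e-15)
})

test_that("RMS arithmetic matches closed forms", {
  x <- sin(2 * pi * 8 * one_sec) # integer periods over the window
  expect_equal(compute_rms(x, fs, full_window), 1 / sqrt(2), tolerance = 1e-4)
  expect_equal(compute_rms(rep(-2, 100), 100, analysis_window(0, 1)), 2)
  expect_equal(compute_rms(c(3, 4), 1, analysis_window(0, 2)), sqrt(25 / 2),
               tolerance = 1e-9)
  expect_error(compute_rms(c(3, 4), 1, analysis_window(0, 0.5)),
               "fewer than 2")
})

test_that("process_trial applies filter, rectify, RMS per electrode", {
  coh <- sample_cohort(1, seed = 6)
  tr <- suppressWarnings(render_trial_signals(coh[1, ], "EF", seed = 6))[[1]]
  rms <- process_trial(tr)
  expect_named(rms, colnames(tr$traces))
  expect_true(all(rms > 0))
  # identical traces on two electrodes give identical RMS
  tr$traces[, "2"] <- tr$traces[, "1"]
  rms2 <- process_trial(tr)
  expect_identical(rms2[["1"]], rms2[["2"]])
  # all-zero trial gives all-zero RMS
  tr$traces[] <- 0
  expect_true(all(process_trial(tr) == 0))
})

test_that("rectification inside the pipeline is an RMS identity", {
  coh <- sample_cohort(1, seed = 8)
  tr <- suppressWarnings(render_trial_signals(coh[1, ], "KE", seed = 8))[[1]]
  w <- analysis_window(0.25, 3.25)
  with_rect <- process_trial(tr, window = w)
  without <- vapply(colnames(tr$traces), function(el) {
    compute_rms(bandpass_filter(tr$traces[, el], tr$sampling_rate),
                tr$sampling_rate, w)
  }, numeric(1))
  expect_equal(with_rect, without, tolerance = 1e-12)
})

test_that("processing is scale-equivariant", {
  coh <- sample_cohort(1, seed = 12)
  tr <- suppressWarnings(render_trial_signals(coh[1, ], "KF", seed = 12))[[1]]
  base <- process_trial(tr)
  tr$traces <- tr$traces * 3.7
  expect_equal(process_trial(tr), base * 3.7, tolerance = 1e-10)
})
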