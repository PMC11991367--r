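test_that("clean beat morphology follows the template", {
  tpl <- beat_template()
  x <- synthesize_beat(tpl, n_samples = 90, sampling_rate = 250)

  # global maximum sits at the sample nearest the R center (+-1 sample)
  r_sample <- round(tpl$centers[["R"]] * 90) + 1
  expect_lte(abs(which.max(x) - r_sample), 1)

  # the U-wave region stays at or below 0.05 mV
  tt <- (seq_len(90) - 1) / 90
  u_support <- abs(tt - tpl$centers[["U"]]) <= 2 * tpl$widths[["U"]]
  expect_lte(max(abs(x[u_support])), 0.05)

  # zero amplitudes leave only the baseline
  flat <- beat_template(amplitudes = c(P = 0, Q = 0, R = 1e-300, S = 0,
                                       T = 0, U = 0),
                        baseline_level = 0.3)
  xb <- synthesize_beat(flat, n_samples = 32)
  expect_equal(as.numeric(xb), rep(0.3, 32), tolerance = 1e-12)

  # deterministic: equal parameters give bit-identical output
  expect_identical(as.numeric(synthesize_beat(tpl)),
                   as.numeric(synthesize_beat(tpl)))
})

test_that("periodic extension yields identical concatenated beats", {
  x2 <- synthesize_beat(beat_template(), n_samples = 180, n_beats = 2)
  expect_identical(as.numeric(x2)[1:90], as.numeric(x2)[91:180])

  # the truncated Fourier view converges to the bump view once every
  # harmonic up to Nyquist is retained
  xb <- synthesize_beat(beat_template(), n_samples = 90)
  xf <- synthesize_beat(beat_template(), n_samples = 90, fourier_terms = 45)
  expect_equal(as.numeric(xf), as.numeric(xb), tolerance = 1e-10)
  xs <- synthesize_beat(beat_template(), n_samples = 90, fourier_terms = 10)
  expect_false(isTRUE(all.equal(as.numeric(xs), as.numeric(xb),
                                tolerance = 1e-6)))
})

test_that("template and beat validation reject bad parameters", {
  expect_error(beat_template(widths = c(P = 0.02, Q = -0.01, R = 0.01,
                                        S = 0.01, T = 0.04, U = 0.03)),
               "widths")
  expect_error(beat_template(centers = c(P = 0.4, Q = 0.36, R = 0.2,
                                         S = 0.44, T = 0.62, U = 0.78)),
               "strictly increase")
  expect_error(beat_template(amplitudes = c(P = 0.1, Q = -0.1, R = 0.2,
                                            S = -0.1, T = 0.5, U = 0.04)),
               "R wave")
  expect_error(synthesize_beat(beat_template(), n_samples = 8), "n_samples")
})

test_that("add_noise is zero-mean Gaussian with the requested scale", {
  x <- as.numeric(synthesize_beat(beat_template()))

  expect_identical(add_noise(x, 0), x)
  expect_identical(add_noise(x, 0.5, seed = 11), add_noise(x, 0.5, seed = 11))
  expect_error(add_noise(x, -0.1), "noise_factor")

  # sample variance of the added noise within 99% chi-square bounds (n = 90)
  d <- add_noise(x, 0.5, seed = 3) - x
  expect_gt(var(d), 0.1)
  expect_lt(var(d), 0.6)

  # zero-mean: |mean| < 4 * noise_factor / sqrt(n) across seeds
  for (s in 1:20) {
    d <- add_noise(x, 0.3, seed = s) - x
    expect_lt(abs(mean(d)), 4 * 0.3 / sqrt(length(x)))
  }
})

test_that("normalization round-trips and guards degenerate input", {
  set.seed(5)
  x <- matrix(rnorm(300), nrow = 10)

  for (mode in c("minus-one-to-one", "zscore", "none")) {
    nr <- normalize_signals(x, mode)
    back <- denormalize_signals(nr$signals, nr$record)
    expect_lt(max(abs(back - x)), 1e-12)
  }

  expect_identical(normalize_signals(x, "none")$signals, x)
  expect_equal(as.numeric(normalize_signals(c(0, 2), "minus-one-to-one")$signals),
               c(-1, 1))

  z <- normalize_signals(rep(0, 50), "zscore")
  expect_equal(as.numeric(z$signals), rep(0, 50))
  expect_equal(z$record$scale, 1)
})

test_that("generate_dataset partitions, normalizes and reproduces", {
  ds <- generate_dataset(n_signals = 100, noise_factor = 0, seed = 2)
  expect_equal(c(nrow(ds$train), nrow(ds$val), nrow(ds$test)), c(80, 10, 10))

  # noiseless: all signals identical, range normalized to [-1, 1]
  expect_equal(max(abs(sweep(ds$train, 2, ds$train[1, ]))), 0)
  expect_equal(min(ds$train), -1)
  expect_equal(max(ds$train), 1)

  # reproducible under the master seed
  ds2 <- generate_dataset(n_signals = 100, noise_factor = 0.2, seed = 9)
  ds3 <- generate_dataset(n_signals = 100, noise_factor = 0.2, seed = 9)
  expect_identical(ds2$train, ds3$train)
  expect_false(identical(
    ds2$train,
    generate_dataset(n_signals = 100, noise_factor = 0.2, seed = 10)$train))

  expect_error(generate_dataset(n_signals = 100, split_fractions = c(0.8, 0.1, 0.2)),
               "sum to 1")
})

test_that("signals survive a CSV round trip", {
  ds <- generate_dataset(n_signals = 20, noise_factor = 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signals(ds$train, path)
  back <- read_signals(path)
  expect_equal(back, ds$train, tolerance = 1e-12)
})
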