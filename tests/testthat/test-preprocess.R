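test_that("resampling preserves duration and tone frequency", {
  x <- make_tone(450, 1, 44100)
  y <- resample_wave(x, 44100, 4000)
  expect_length(y, 4000L)
  expect_equal(fft_peak_hz(y, 4000), 450, tolerance = 2)
  expect_identical(resample_wave(x, 44100, 44100), x)
})

test_that("padding reaches exactly six seconds at 4 kHz and is idempotent", {
  cfg <- pad_config()
  p <- pad_or_truncate(rnorm(9572), cfg)
  expect_length(p, 24000L)
  expect_equal(p[9573:24000], numeric(14428))
  expect_identical(pad_or_truncate(p, cfg), p)
  long <- rnorm(16 * 4000)
  expect_identical(pad_or_truncate(long, cfg), long[1:24000])
  expect_error(pad_or_truncate(numeric(0), cfg), "empty")
})

test_that("time stretch scales duration without moving the pitch", {
  x <- make_tone(450, 6)
  expect_identical(time_stretch(x, 1), x)
  y <- time_stretch(x, 1.2)
  expect_lte(abs(length(y) - round(1.2 * 24000)), 2)
  expect_equal(fft_peak_hz(y, 4000), 450, tolerance = 0.02 * 450)
  z <- time_stretch(x, 0.8)
  expect_lte(abs(length(z) - round(0.8 * 24000)), 2)
  expect_error(time_stretch(x, 0), "positive")
})

test_that("pitch shift scales frequencies by 2^u at constant length", {
  x <- make_tone(450, 2)
  expect_gt(stats::cor(pitch_shift(x, 4000, max_shift = 0), x), 0.99)
  y <- pitch_shift(x, 4000, shift = 0.2)
  expect_length(y, length(x))
  expect_equal(fft_peak_hz(y, 4000), 450 * 2^0.2, tolerance = 0.02 * 450 * 2^0.2)
  dn <- pitch_shift(x, 4000, shift = -0.2)
  expect_equal(fft_peak_hz(dn, 4000), 450 * 2^-0.2, tolerance = 0.02 * 450)
  expect_identical(pitch_shift(x, 4000, seed = 3), pitch_shift(x, 4000, seed = 3))
})

test_that("additive noise has the configured scale and is input-independent", {
  x <- make_tone(200, 6)
  expect_identical(add_noise(x, 0), x)
  y <- add_noise(numeric(24000), 0.005, seed = 1)
  expect_gte(sd(y), 0.0045)
  expect_lte(sd(y), 0.0055)
  expect_identical(add_noise(x, 0.005, seed = 2), add_noise(x, 0.005, seed = 2))
  # the injected noise does not depend on the carrier signal
  a <- add_noise(x, 0.005, seed = 9) - x
  b <- add_noise(numeric(length(x)), 0.005, seed = 9)
  expect_equal(a, b)
})

test_that("augmentation multiplies per-class counts and inherits labels", {
  cfg <- tiny_config(seed = 6L, duration_range = c(0.3, 0.6))
  cyc <- synth_cycles(4, cfg)                      # 4 per class, 16 total
  out <- augment_dataset(cyc, augment_params(seed = 1),
                         multiplicity = c(W = 3, B = 1))
  expect_equal(nrow(out), 16 + 4 * 3 + 4 * 1)
  expect_equal(sum(out$cycle_label == "W"), 16)
  expect_equal(sum(out$cycle_label == "B"), 8)
  expect_true(all(out$augmented[-(1:16)]))
  expect_identical(augment_dataset(cyc, multiplicity = c(N = 0)), cyc)
  expect_error(augment_dataset(cyc, multiplicity = c(W = -1)), ">= 0")
})

test_that("augmented copies re-pad to the fixed length with labels intact", {
  cfg <- tiny_config(seed = 8L, duration_range = c(0.5, 1))
  cyc <- synth_cycles(2, cfg, labels = c("W", "C"))
  aug <- augment_dataset(cyc, augment_params(seed = 2), c(W = 3, C = 3))
  pp <- preprocess_cycles(aug)
  expect_true(all(lengths(pp$waveform) == 24000L))
  expect_equal(pp$cycle_label, aug$cycle_label)
})
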