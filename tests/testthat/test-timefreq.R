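test_that("the spectrogram obeys frame-count, nullity and Parseval identities", {
  p <- stft_params()
  g <- stft_spectrogram(numeric(24000), p)
  expect_equal(dim(g), c(257L, 1L + (24000L - 512L) %/% p$hop_length))
  expect_equal(ncol(g), 184L)
  expect_true(all(g == 0))
  tone <- make_tone(450, 6)
  gt <- stft_spectrogram(tone, p)
  freqs <- (seq_len(nrow(gt)) - 1) * 4000 / 512
  peaks <- freqs[apply(gt, 2, which.max)]
  expect_true(all(abs(peaks - 450) <= 4000 / 512))
  # Parseval: rectangular window, hop = window, full spectrum
  x <- rnorm(1024)
  pr <- stft_params(window_length = 256, hop_length = 256, window = "rectangular")
  gr <- stft_spectrogram(x, pr, onesided = FALSE)
  expect_equal(sum(gr) / 256, sum(x^2), tolerance = 1e-6)
  expect_error(stft_spectrogram(rnorm(100), p), "shorter")
})

test_that("hz_to_mel matches the closed form and is strictly increasing", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  expect_equal(hz_to_mel(700), 781.1717, tolerance = 1e-4)
  withr::local_seed(3)
  f <- sort(runif(100, 0, 8000))
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_error(hz_to_mel(-1), "non-negative")
  expect_equal(mel_to_hz(hz_to_mel(c(25, 450, 2000))), c(25, 450, 2000))
})

test_that("the mel filterbank has positive rows and mel-uniform centers", {
  fb <- mel_filterbank()
  expect_equal(dim(fb), c(128L, 257L))
  expect_true(all(rowSums(fb) > 0))
  centers <- hz_to_mel(attr(fb, "center_freqs"))
  expect_lt(max(abs(diff(centers) - diff(centers)[1])), 1e-6)
})

test_that("mel scalograms are 128x128 images peaking at the tone's band", {
  img <- mel_scalogram(make_tone(450, 6))
  expect_s3_class(img, "lung_scalogram")
  expect_equal(dim(img), c(128L, 128L))
  expect_true(all(img >= 0 & img <= 1))
  fb <- mel_filterbank()
  centers <- attr(fb, "center_freqs")
  # peak of the un-resized band energies lies within one band of 450 Hz
  bands <- fb %*% stft_spectrogram(make_tone(450, 6))
  k <- which.max(rowMeans(bands))
  expect_lte(abs(hz_to_mel(centers[k]) - hz_to_mel(450)),
             1.5 * diff(hz_to_mel(centers[1:2])))
  # zero signal: normalization guard gives a flat half-intensity image
  expect_true(all(mel_scalogram(numeric(24000)) == 0.5))
})

test_that("image rendering normalises, guards constants and resizes", {
  expect_true(all(to_image(matrix(3.7, 10, 10)) == 0.5))
  withr::local_seed(4)
  g <- matrix(runif(200, 1, 5), 10, 20)
  img <- to_image(g, size = 128)
  expect_equal(dim(img), c(128L, 128L))
  expect_true(all(img >= 0 & img <= 1))
  # without resizing, normalisation spans [0, 1] exactly
  g128 <- matrix(runif(128 * 128, 1, 5), 128)
  expect_equal(range(to_image(g128, size = 128)), c(0, 1), tolerance = 1e-12)
  m <- matrix(runif(128 * 128), 128)
  expect_equal(resize_bilinear(m, 128, 128), m)
  expect_error(to_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("transform_cycles emits aligned image columns per branch", {
  cyc <- preprocess_cycles(synth_cycles(2, tiny_config(seed = 3L),
                                        labels = c("N", "W")))
  imgs <- transform_cycles(cyc, branch = "both")
  expect_named(imgs, c(setdiff(names(cyc), "waveform"), "mel", "cwt"),
               ignore.order = TRUE)
  expect_equal(dim(imgs$mel[[1]]), dim(imgs$cwt[[1]]))
  expect_equal(nrow(imgs), 4L)
})
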