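test_that("synthetic wheezes are enveloped tones in the 400-500 Hz band", {
  withr::local_seed(1)
  w <- synth_wheeze(0.3, 450, 4000)
  expect_length(w, 1200L)
  expect_equal(fft_peak_hz(w, 4000), 450, tolerance = 4000 / 1200 + 1e-9)
  expect_error(synth_wheeze(0.05, 450, 4000), "100 ms")
  expect_error(synth_wheeze(0.3, 350, 4000), "400-500")
  expect_equal(synth_wheeze(0.3, 450, 4000, amplitude = 0), numeric(1200))
})

test_that("synthetic crackles are short damped bursts with in-band pitch", {
  withr::local_seed(1)
  cr <- synth_crackle(4000, 800)
  expect_lte(length(cr), 80L)                       # <= 20 ms at 4 kHz
  spec <- Mod(fft(c(cr, numeric(4096 - length(cr)))))[1:2049]
  centroid <- sum((0:2048) * 4000 / 4096 * spec) / sum(spec)
  expect_gte(centroid, 100)
  expect_lte(centroid, 2000)
  expect_error(synth_crackle(4000, 50), "100-2000")
  expect_identical(withr::with_seed(7, synth_crackle(4000, 800)),
                   withr::with_seed(7, synth_crackle(4000, 800)))
})

test_that("cycle labels control event content via band energy", {
  cfg <- synth_config(seed = 5L)
  band_db <- function(x) {
    bf <- signal::butter(4, c(400, 500) / (cfg$sample_rate / 2), "pass")
    10 * log10(mean(signal::filtfilt(bf, as.numeric(x))^2))
  }
  withr::local_seed(5)
  n_db <- replicate(5, band_db(synth_cycle("N", cfg, duration = 2)))
  w_db <- replicate(5, band_db(synth_cycle("W", cfg, duration = 2)))
  expect_gte(mean(w_db) - mean(n_db), 6)
  b <- synth_cycle("B", cfg, duration = 2)
  expect_gte(band_db(b) - mean(n_db), 6)
})

test_that("band-energy classifier separates N from W on 200 cycles", {
  # guarantees the downstream pipeline has signal to learn
  cfg <- synth_config(seed = 2L)
  cyc <- synth_cycles(100, cfg, labels = c("N", "W"))
  rel_db <- vapply(cyc$waveform, function(w) {
    bf <- signal::butter(4, c(400, 500) / (cfg$sample_rate / 2), "pass")
    10 * log10(mean(signal::filtfilt(bf, w)^2) / mean(w^2))
  }, numeric(1))
  is_w <- cyc$cycle_label == "W"
  thr <- (mean(rel_db[is_w]) + mean(rel_db[!is_w])) / 2
  expect_gte(mean((rel_db > thr) == is_w), 0.95)
})

test_that("synthetic datasets are deterministic and self-consistent", {
  root1 <- withr::local_tempdir(); root2 <- withr::local_tempdir()
  m1 <- synth_dataset(tiny_config(seed = 9L), root1)
  m2 <- synth_dataset(tiny_config(seed = 9L), root2)
  expect_identical(m1, m2)
  for (f in list.files(root1)) {
    expect_identical(readBin(file.path(root1, f), "raw", file.size(file.path(root1, f))),
                     readBin(file.path(root2, f), "raw", file.size(file.path(root2, f))),
                     label = paste("bytes of", f))
  }
  cyc <- load_dataset(root1, verbose = FALSE)
  expect_equal(nrow(cyc), sum(m1$n_cycles))
  # annotations all satisfy the parser's invariants (load succeeded), and
  # Healthy patients contribute only normal cycles
  healthy <- m1$patient_id[m1$disease == "Healthy"]
  expect_true(all(cyc$cycle_label[cyc$patient_id %in% healthy] == "N"))
})

test_that("a degenerate class mix yields only normal cycles", {
  root <- withr::local_tempdir()
  cfg <- tiny_config(seed = 2L,
                     class_mix = c(N = 1, C = 0, W = 0, B = 0))
  synth_dataset(cfg, root)
  cyc <- load_dataset(root, verbose = FALSE)
  expect_true(all(cyc$cycle_label == "N"))
})

test_that("synth_config validates its probability vectors", {
  expect_error(synth_config(class_mix = c(N = 0.5, C = 0.5, W = 0.5, B = 0.5)),
               "sum to 1")
  expect_error(synth_config(disease_mix = c(Healthy = 1)), "8 disease")
})
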