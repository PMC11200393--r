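test_that("annotation files parse row by row with order preserved", {
  ann <- read_annotation_file(example_annotation_path())
  expect_equal(nrow(ann), 8L)
  expect_equal(ann$start_time[1], 1.018)
  expect_equal(ann$end_time[8], 19.542)
  # row 03 carries both crackle and wheeze flags
  expect_equal(unlist(ann[3, ]), c(start_time = 5.827, end_time = 8.339,
                                   crackles = 1, wheezes = 1))
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_equal(nrow(read_annotation_file(empty)), 0L)
})

test_that("malformed annotation rows fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0\t1.0\t0\t0", "1.0\t2.0\t1"), f)
  expect_error(read_annotation_file(f), "line 2.*4 columns")
  writeLines(c("0.0\t1.0\t0\t0", "1.0\tabc\t0\t0"), f)
  expect_error(read_annotation_file(f), "line 2.*non-numeric")
  writeLines("2.0\t1.0\t0\t0", f)
  expect_error(read_annotation_file(f), "line 1.*end time")
  writeLines("0.0\t1.0\t2\t0", f)
  expect_error(read_annotation_file(f), "flags")
})

test_that("annotation write/read round trip preserves values to 3 decimals", {
  ann <- tibble::tibble(start_time = c(0, 1.23456), end_time = c(1.23456, 2.5),
                        crackles = c(1L, 0L), wheezes = c(0L, 1L))
  f <- withr::local_tempfile(fileext = ".txt")
  write_annotation_file(ann, f)
  back <- read_annotation_file(f)
  expect_equal(back$start_time, round(ann$start_time, 3))
  expect_equal(back$end_time, round(ann$end_time, 3))
  expect_equal(back$crackles, ann$crackles)
  expect_equal(back$wheezes, ann$wheezes)
})

test_that("segmentation extracts half-open sample windows with N/C/W/B labels", {
  ann <- read_annotation_file(example_annotation_path())
  fs <- 4000
  wav <- rnorm(round(19.542 * fs) + 1)
  cyc <- segment_cycles(wav, fs, ann, patient_id = "101", recording_id = "101_r1")
  expect_equal(nrow(cyc), 8L)
  expect_equal(cyc$cycle_label[3], "B")
  expect_equal(cyc$cycle_label[5], "W")
  expect_equal(cyc$cycle_label[c(1, 2, 4, 6, 7, 8)], rep("C", 6))
  # cycle 01 spans [round(1.018 fs), round(3.411 fs)) = 9572 samples
  expect_length(cyc$waveform[[1]], 9572L)
  # full-span normal cycle at 4 kHz
  one <- segment_cycles(rnorm(4000), 4000,
                        tibble::tibble(start_time = 0, end_time = 1,
                                       crackles = 0, wheezes = 0))
  expect_length(one$waveform[[1]], 4000L)
  expect_equal(one$cycle_label, "N")
})

test_that("segmentation rejects annotations beyond the recording", {
  ann <- tibble::tibble(start_time = 0, end_time = 2, crackles = 0, wheezes = 0)
  expect_error(segment_cycles(rnorm(4000), 4000, ann), "beyond the recording")
})

test_that("gapless segmentation conserves the spanned samples exactly", {
  fs <- 4000
  wav <- rnorm(2 * fs)
  ann <- tibble::tibble(start_time = c(0, 0.5, 1.25), end_time = c(0.5, 1.25, 2),
                        crackles = 0, wheezes = 0)
  cyc <- segment_cycles(wav, fs, ann)
  expect_identical(unlist(cyc$waveform), wav)
})

test_that("WAV files round-trip through the PCM16 codec", {
  x <- sin(2 * pi * 440 * (0:7999) / 8000) * 0.7
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 8000, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$waveform, x, tolerance = 1e-4)
})

test_that("load_dataset joins diagnosis and partitions labels over N/C/W/B", {
  root <- withr::local_tempdir()
  manifest <- synth_dataset(tiny_config(seed = 3L), root)
  cyc <- suppressMessages(load_dataset(root, verbose = FALSE))
  expect_equal(nrow(cyc), sum(manifest$n_cycles))
  expect_true(all(!is.na(cyc$disease_label)))
  counts <- table(factor(cyc$cycle_label, levels = c("N", "C", "W", "B")))
  expect_equal(sum(counts), nrow(cyc))
  # label flags reconstruct the labels
  expect_equal(cycle_label_from_flags(cyc$crackles, cyc$wheezes), cyc$cycle_label)
})

test_that("unpaired recordings are skipped with a warning", {
  root <- withr::local_tempdir()
  synth_dataset(tiny_config(seed = 4L), root)
  writeLines("0.0\t0.5\t0\t0", file.path(root, "999_r1.txt"))
  expect_warning(load_dataset(root, verbose = FALSE), "unpaired.*999_r1")
})
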