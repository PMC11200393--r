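#' Segment a recording into labelled respiratory cycles
#'
#' Cycle *k* takes the half-open sample interval
#' `[round(start * fs), round(end * fs))`, so gapless annotations partition
#' the spanned waveform without duplicating boundary samples. The cycle label
#' is derived from the crackle/wheeze flags (N / C / W / B).
#'
#' @param waveform Numeric amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param annotations Tibble as returned by [read_annotation_file()].
#' @param patient_id,recording_id Provenance identifiers attached to each cycle.
#' @return A `lung_cycles` tibble, one row per cycle, with the annotation
#'   columns plus `cycle_label`, `sample_rate` and a `waveform` list-column.
#' @export
segment_cycles <- function(waveform, sample_rate, annotations,
                           patient_id = NA_character_,
                           recording_id = NA_character_) {
  n <- length(waveform)
  i0 <- round(annotations$start_time * sample_rate)
  i1 <- round(annotations$end_time * sample_rate)
  over <- which(i1 > n + 1L)                       # tolerance: one sample
  if (length(over))
    stop("annotation cycle(s) ", paste(over, collapse = ", "),
         " extend beyond the recording (", n, " samples at ",
         sample_rate, " Hz)")
  i1 <- pmin(i1, n)
  cycles <- tibble::tibble(
    patient_id   = as.character(patient_id),
    recording_id = as.character(recording_id),
    cycle_index  = seq_len(nrow(annotations)),
    start_time   = annotations$start_time,
    end_time     = annotations$end_time,
    crackles     = as.integer(annotations$crackles),
    wheezes      = as.integer(annotations$wheezes),
    cycle_label  = cycle_label_from_flags(annotations$crackles, annotations$wheezes),
    disease_label = NA_character_,
    sample_rate  = as.numeric(sample_rate),
    augmented    = FALSE,
    waveform     = purrr::map2(i0, i1, function(a, b) waveform[(a + 1L):b])
  )
  as_lung_cycles(cycles)
}

as_lung_cycles <- function(x) {
  class(x) <- unique(c("lung_cycles", class(x)))
  x
}

#' Read a patient diagnosis table
#'
#' Expects a CSV with columns `patient_id` and `disease` (renameable through
#' `col_map` for other dialects, e.g. the headerless two-column file shipped
#' with ICBHI-2017 can be read with `header = FALSE`).
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping `c(patient_id=, disease=)`
#'   onto the file's column names.
#' @param header Does the file have a header row?
#' @return Tibble with `patient_id`, `disease`.
#' @export
read_diagnosis_file <- function(path,
                                col_map = c(patient_id = "patient_id",
                                            disease = "disease"),
                                header = TRUE) {
  df <- read.csv(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df)[1:2] <- c(col_map[["patient_id"]], col_map[["disease"]])
  missing_cols <- setdiff(unname(col_map), names(df))
  if (length(missing_cols))
    stop("diagnosis table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- tibble::tibble(patient_id = as.character(df[[col_map[["patient_id"]]]]),
                        disease = as.character(df[[col_map[["disease"]]]]))
  unknown <- setdiff(unique(out$disease), DISEASE_LEVELS)
  if (length(unknown))
    warning("disease label(s) outside the 8-class vocabulary: ",
            paste(unknown, collapse = ", "))
  out
}

#' Load an ICBHI-layout dataset directory
#'
#' Pairs each `X.wav` with its `X.txt` annotation, segments every recording
#' into labelled cycles, and joins the per-patient diagnosis table. The
#' patient id is the token before the first underscore of the file stem
#' (ICBHI convention).
#'
#' @param root Directory containing WAV + annotation files and (optionally) a
#'   `diagnosis.csv`.
#' @param diagnosis Path to the diagnosis CSV; defaults to
#'   `file.path(root, "diagnosis.csv")` when present.
#' @param verbose Log a per-label summary?
#' @return A `lung_cycles` tibble over all recordings.
#' @export
load_dataset <- function(root, diagnosis = NULL, verbose = TRUE) {
  wavs <- sort(list.files(root, pattern = "\\.wav$", full.names = TRUE))
  txts <- sort(list.files(root, pattern = "\\.txt$", full.names = TRUE))
  stems <- function(p) sub("\\.[^.]+$", "", basename(p))
  paired <- intersect(stems(wavs), stems(txts))
  orphan <- c(setdiff(stems(wavs), stems(txts)), setdiff(stems(txts), stems(wavs)))
  if (length(orphan))
    warning("skipping unpaired recording(s): ", paste(orphan, collapse = ", "))
  if (!length(paired)) stop("no paired WAV/annotation files under ", root)

  cycles <- purrr::map(paired, function(stem) {
    wav <- read_wav(file.path(root, paste0(stem, ".wav")))
    ann <- read_annotation_file(file.path(root, paste0(stem, ".txt")))
    segment_cycles(wav$waveform, wav$sample_rate, ann,
                   patient_id = strsplit(stem, "_")[[1]][1],
                   recording_id = stem)
  })
  cycles <- dplyr::bind_rows(cycles)

  if (is.null(diagnosis)) {
    cand <- file.path(root, "diagnosis.csv")
    if (file.exists(cand)) diagnosis <- cand
  }
  if (!is.null(diagnosis)) {
    diag <- read_diagnosis_file(diagnosis)
    cycles$disease_label <- diag$disease[match(cycles$patient_id, diag$patient_id)]
  }
  if (verbose) {
    counts <- table(factor(cycles$cycle_label, levels = CYCLE_LEVELS))
    message("loaded ", nrow(cycles), " cycles from ", length(paired),
            " recordings (", paste(names(counts), counts, sep = "=", collapse = " "), ")")
  }
  as_lung_cycles(cycles)
}
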