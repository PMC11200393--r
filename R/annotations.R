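#' Read an ICBHI-style cycle annotation file
#'
#' Annotation files hold one respiratory cycle per row, whitespace- or
#' tab-delimited: start time (s), end time (s), crackle flag, wheeze flag.
#'
#' @param path Path to the annotation text file.
#' @return A tibble with one row per cycle: `start_time`, `end_time`,
#'   `crackles`, `wheezes`, in file order. An empty file yields zero rows.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("0.0\t1.2\t1\t0", f)
#' read_annotation_file(f)
#' @export
read_annotation_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) != 4L)
      stop("line ", i, " of '", basename(path), "': expected 4 columns, got ",
           length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop("line ", i, " of '", basename(path), "': non-numeric field")
    vals
  })
  ann <- if (length(rows)) {
    m <- do.call(rbind, rows)
    tibble::tibble(start_time = m[, 1], end_time = m[, 2],
                   crackles = as.integer(m[, 3]), wheezes = as.integer(m[, 4]))
  } else {
    tibble::tibble(start_time = numeric(), end_time = numeric(),
                   crackles = integer(), wheezes = integer())
  }
  validate_annotations(ann, path = path, lines = keep)
  ann
}

validate_annotations <- function(ann, path = "<annotation>", lines = seq_len(nrow(ann))) {
  bad <- which(!(ann$crackles %in% c(0L, 1L)) | !(ann$wheezes %in% c(0L, 1L)))
  if (length(bad))
    stop("line ", lines[bad[1]], " of '", basename(path),
         "': crackle/wheeze flags must be 0 or 1")
  bad <- which(ann$end_time <= ann$start_time | ann$start_time < 0)
  if (length(bad))
    stop("line ", lines[bad[1]], " of '", basename(path),
         "': end time must exceed a non-negative start time")
  long <- which(ann$end_time - ann$start_time > 16 + 1e-9)
  if (length(long))
    warning(length(long), " cycle(s) in '", basename(path),
            "' exceed the expected 16 s maximum duration")
  short <- which(ann$end_time - ann$start_time < 0.2 - 1e-9)
  if (length(short))
    warning(length(short), " cycle(s) in '", basename(path),
            "' shorter than 0.2 s are kept")
  invisible(ann)
}

#' Write a cycle annotation file
#'
#' Inverse of [read_annotation_file()]; times are written with three decimals,
#' tab-delimited, so a read/write round trip preserves the numeric content at
#' millisecond resolution.
#'
#' @param annotations Tibble/data frame with `start_time`, `end_time`,
#'   `crackles`, `wheezes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_file <- function(annotations, path) {
  lines <- sprintf("%.3f\t%.3f\t%d\t%d",
                   annotations$start_time, annotations$end_time,
                   as.integer(annotations$crackles), as.integer(annotations$wheezes))
  writeLines(lines, path)
  invisible(path)
}

#' Derive the N/C/W/B cycle label from crackle and wheeze flags
#'
#' @param crackles,wheezes Binary flags (0/1), vectorised.
#' @return Character vector over `"N"`, `"C"`, `"W"`, `"B"`.
#' @export
cycle_label_from_flags <- function(crackles, wheezes) {
  dplyr::case_when(
    crackles == 1 & wheezes == 1 ~ "B",
    crackles == 1 ~ "C",
    wheezes  == 1 ~ "W",
    .default = "N"
  )
}
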