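#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for PCM 16-bit and IEEE float mono/stereo files,
#' the formats used by digital stethoscope exports. Multi-channel files are
#' reduced to channel 1 with a warning; samples are returned as doubles
#' nominally in \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `waveform` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")           # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate      = readBin(con, "integer", 1, 4, endian = "little"),
        block_align    = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits_per_sample = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)            # pad byte
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  if (fmt$audio_format == 1L && fmt$bits_per_sample == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits_per_sample == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4L, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits_per_sample, " bit) in ", path)
  }
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV '", basename(path), "': keeping channel 1")
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  list(waveform = x, sample_rate = fmt$sample_rate)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param waveform Numeric vector of samples; values are clipped to \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmin(pmax(waveform, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                   # PCM
  writeBin(1L, con, 2L, endian = "little")                   # mono
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
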