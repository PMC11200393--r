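#' STFT parameters
#'
#' Defaults (Hann window of 512 samples, hop 128 at 4000 Hz, i.e. 128 ms
#' windows with 75% overlap) are chosen so a padded 6 s cycle yields 184
#' frames, at least the 128 columns of the rendered image.
#'
#' @param window_length,hop_length Samples; `0 < hop_length <= window_length`.
#' @param window Taper name (`"hann"` or `"rectangular"`).
#' @export
stft_params <- function(window_length = 512L, hop_length = 128L,
                        window = c("hann", "rectangular")) {
  window <- match.arg(window)
  stopifnot(hop_length > 0, hop_length <= window_length)
  list(window_length = as.integer(window_length),
       hop_length = as.integer(hop_length), window = window)
}

#' Mel filterbank parameters
#'
#' 128 bands spanning 25--2000 Hz (the Nyquist band at the common 4000 Hz
#' rate), matching the 128-row scalogram image.
#'
#' @param n_mels Number of triangular bands.
#' @param f_min,f_max Band-edge frequency range in Hz.
#' @param log_floor Additive floor before the log compression.
#' @export
mel_params <- function(n_mels = 128L, f_min = 25, f_max = 2000,
                       log_floor = 1e-10) {
  stopifnot(f_min >= 0, f_min < f_max, log_floor > 0)
  list(n_mels = as.integer(n_mels), f_min = f_min, f_max = f_max,
       log_floor = log_floor)
}

#' Magnitude-squared short-time Fourier spectrogram
#'
#' Each column is `|FFT(windowed frame)|^2`; the frame count is
#' `1 + floor((n - window_length) / hop_length)`.
#'
#' @param waveform Numeric vector, at least one window long.
#' @param params An [stft_params()].
#' @param onesided Keep only bins up to Nyquist (default) or the full circle.
#' @return Matrix, frequency bins x frames.
#' @export
stft_spectrogram <- function(waveform, params = stft_params(), onesided = TRUE) {
  n_fft <- params$window_length
  if (length(waveform) < n_fft)
    stop("waveform (", length(waveform), " samples) shorter than the ",
         n_fft, "-sample analysis window")
  win <- switch(params$window,
                hann = hann_window(n_fft),
                rectangular = rep(1, n_fft))
  frames <- stft_frames(waveform, win, params$hop_length)
  p <- Mod(frames)^2
  if (onesided) p <- p[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
  p
}

#' Hertz to mel conversion
#'
#' `M = 2595 * log10(1 + f / 700)`, the standard perceptual mapping; strictly
#' increasing, with 0 Hz at 0 mel.
#'
#' @param f Frequency in Hz (vectorised, non-negative).
#' @return Mel values.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequencies must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel to hertz conversion (inverse of [hz_to_mel()])
#' @param m Mel values.
#' @return Frequencies in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' Band centres are uniformly spaced on the mel scale between `f_min` and
#' `f_max`; each row is a triangle over the FFT bin frequencies. A row whose
#' triangle is narrower than the bin spacing gets unit weight at the bin
#' nearest its centre so every band keeps positive mass.
#'
#' @param mel A [mel_params()].
#' @param n_fft FFT length behind the spectrogram.
#' @param sample_rate Hz.
#' @return `n_mels x (n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(mel = mel_params(), n_fft = 512L, sample_rate = 4000) {
  n_bins <- n_fft %/% 2 + 1L
  bin_freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(mel$f_min), hz_to_mel(mel$f_max),
                         length.out = mel$n_mels + 2L))
  fb <- matrix(0, mel$n_mels, n_bins)
  for (m in seq_len(mel$n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
    if (sum(fb[m, ]) == 0)
      fb[m, which.min(abs(bin_freqs - ce))] <- 1
  }
  attr(fb, "center_freqs") <- edges[2:(mel$n_mels + 1L)]
  fb
}

#' Log-mel scalogram image of a padded cycle
#'
#' The magnitude-squared STFT grid is pooled through the triangular mel
#' filterbank, log-compressed, min-max normalised and bilinearly resized to a
#' 128 x 128 image (rows = mel bands, low frequencies at row 1; columns =
#' time).
#'
#' @param waveform Fixed-length numeric vector at `sample_rate`.
#' @param stft An [stft_params()].
#' @param mel A [mel_params()].
#' @param sample_rate Hz.
#' @param size Output image side length.
#' @return A `lung_scalogram` matrix in \[0, 1\].
#' @export
mel_scalogram <- function(waveform, stft = stft_params(), mel = mel_params(),
                          sample_rate = 4000, size = 128L) {
  p <- stft_spectrogram(waveform, stft)
  fb <- mel_filterbank(mel, stft$window_length, sample_rate)
  to_image(fb %*% p, size = size, log_floor = mel$log_floor, branch = "mel")
}

#' Transform a cycle tibble into scalogram images
#'
#' @param cycles A preprocessed `lung_cycles` tibble (fixed-length waveforms).
#' @param branch `"mel"`, `"cwt"`, or `"both"`.
#' @param stft,mel,cwt Parameter lists for the two branches.
#' @param size Image side length.
#' @return The input tibble (waveforms dropped) with list-columns `mel`
#'   and/or `cwt` holding `lung_scalogram` matrices.
#' @export
transform_cycles <- function(cycles, branch = c("both", "mel", "cwt"),
                             stft = stft_params(), mel = mel_params(),
                             cwt = cwt_params(), size = 128L) {
  branch <- match.arg(branch)
  fs <- unique(cycles$sample_rate)
  if (length(fs) != 1)
    stop("cycles must share one sample rate; run preprocess_cycles() first")
  out <- dplyr::select(cycles, -"waveform")
  if (branch %in% c("both", "mel"))
    out$mel <- purrr::map(cycles$waveform, mel_scalogram,
                          stft = stft, mel = mel, sample_rate = fs, size = size)
  if (branch %in% c("both", "cwt"))
    out$cwt <- purrr::map(cycles$waveform, cwt_scalogram,
                          params = cwt, sample_rate = fs, size = size)
  out
}
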