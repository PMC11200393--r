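#' Continuous wavelet transform parameters
#'
#' The analysing wavelet is a complex Morlet
#' `psi(t) = (pi * bandwidth)^(-1/2) * exp(2i * pi * center_freq * t) *
#' exp(-t^2 / bandwidth)`. Scales form a geometric grid whose
#' pseudo-frequencies (`center_freq * fs / s`) span `freq_range`.
#'
#' @param n_scales Number of scales (default 128, matching the image rows).
#' @param freq_range Pseudo-frequency span in Hz.
#' @param center_freq Dimensionless Morlet centre-frequency parameter.
#' @param bandwidth Dimensionless Morlet bandwidth parameter.
#' @param hop Translation step in samples for the scalogram grid (default
#'   128, matching the STFT hop; 188 columns for a 6 s cycle at 4 kHz).
#' @export
cwt_params <- function(n_scales = 128L, freq_range = c(25, 2000),
                       center_freq = 1.0, bandwidth = 1.5, hop = 128L) {
  stopifnot(n_scales >= 1, freq_range[1] > 0, freq_range[2] > freq_range[1],
            center_freq > 0, bandwidth > 0, hop >= 1)
  list(n_scales = as.integer(n_scales), freq_range = freq_range,
       center_freq = center_freq, bandwidth = bandwidth, hop = as.integer(hop))
}

#' Scale grid and pseudo-frequencies for a CWT configuration
#' @param params A [cwt_params()].
#' @param sample_rate Hz.
#' @return Tibble with `scale` (samples, increasing) and `pseudo_freq` (Hz,
#'   decreasing).
#' @export
cwt_scales <- function(params = cwt_params(), sample_rate = 4000) {
  freqs <- exp(seq(log(params$freq_range[2]), log(params$freq_range[1]),
                   length.out = params$n_scales))
  tibble::tibble(scale = params$center_freq * sample_rate / freqs,
                 pseudo_freq = freqs)
}

# Sampled complex Morlet daughter wavelet (1/sqrt(s) normalisation) on an
# integer grid covering its effective support; used by the direct-sum path.
morlet_daughter <- function(s, params) {
  half <- ceiling(4 * sqrt(params$bandwidth) * s)
  u <- (-half):half
  t <- u / s
  psi <- (pi * params$bandwidth)^(-0.5) *
    exp(2i * pi * params$center_freq * t) * exp(-t^2 / params$bandwidth)
  list(values = psi / sqrt(s), offsets = u)
}

#' Raw complex-Morlet CWT magnitudes
#'
#' Computes `|CWT(s, t)| = |1/sqrt(s) * sum_tau x(tau) psi*((tau - t) / s)|`
#' on the scale grid of [cwt_scales()], sampled every `params$hop` samples in
#' time. The convolution runs in the frequency domain using the Morlet's
#' closed-form Gaussian spectrum, with zero-padding past the wavelet support
#' so the result equals the direct sum up to sampling error.
#'
#' @param waveform Numeric vector.
#' @param params A [cwt_params()].
#' @param sample_rate Hz.
#' @param oversample Translations evaluated per hop (when the hop is
#'   divisible by it); the magnitudes within each hop block are max-pooled,
#'   so short transients (crackles are ~16 ms) register regardless of where
#'   they fall relative to the translation grid. `hop = 1` disables pooling.
#' @return `n_scales x n_translations` magnitude matrix; rows follow
#'   [cwt_scales()] order (high to low pseudo-frequency); attribute
#'   `pseudo_freqs` carries the row frequencies.
#' @export
cwt_magnitudes <- function(waveform, params = cwt_params(), sample_rate = 4000,
                           oversample = 4L) {
  n <- length(waveform)
  grid <- cwt_scales(params, sample_rate)
  s_max <- max(grid$scale)
  hop <- params$hop
  if (hop %% oversample != 0L) oversample <- 1L
  sub <- hop %/% oversample
  pad <- ceiling(8 * sqrt(params$bandwidth) * s_max)
  nfft <- hop * ceiling((n + pad) / hop)
  n_cols <- ceiling(n / hop)
  n_fine <- n_cols * oversample
  m_dec <- nfft %/% sub

  X <- fft(c(waveform, numeric(nfft - n)))
  # frequency response of h(v) = conj(psi)(-v/s)/sqrt(s):
  # H(f) = sqrt(s) * exp(-pi^2 * B * (s f - C)^2), f in cycles/sample
  f_grid <- (seq_len(nfft) - 1) / nfft
  f_grid[f_grid > 0.5] <- f_grid[f_grid > 0.5] - 1
  out <- matrix(0, params$n_scales, n_cols)
  for (r in seq_len(params$n_scales)) {
    s <- grid$scale[r]
    expo <- -pi^2 * params$bandwidth * (s * f_grid - params$center_freq)^2
    band <- which(expo > -40)
    Z <- complex(length.out = nfft)
    Z[band] <- X[band] * (sqrt(s) * exp(expo[band]))
    # decimate-by-folding: IFFT of the aliased spectrum gives y[m * sub]
    fold <- rowSums(matrix(Z, m_dec, nfft %/% m_dec))
    y <- Mod(fft(fold, inverse = TRUE))[seq_len(n_fine)] / nfft
    out[r, ] <- if (oversample == 1L) y
                else apply(matrix(y, oversample, n_cols), 2, max)
  }
  attr(out, "pseudo_freqs") <- grid$pseudo_freq
  out
}

# Direct Riemann-sum evaluation of the CWT at unit time step; quadratic cost,
# used as the independent check of the spectral path on short signals.
cwt_direct <- function(waveform, params = cwt_params(), sample_rate = 4000,
                       hop = 1L) {
  n <- length(waveform)
  grid <- cwt_scales(params, sample_rate)
  times <- seq(1L, n, by = hop)
  out <- matrix(0, params$n_scales, length(times))
  for (r in seq_len(params$n_scales)) {
    d <- morlet_daughter(grid$scale[r], params)
    for (k in seq_along(times)) {
      tau <- times[k] + d$offsets
      ok <- tau >= 1 & tau <= n
      out[r, k] <- Mod(sum(waveform[tau[ok]] * Conj(d$values[ok])))
    }
  }
  attr(out, "pseudo_freqs") <- grid$pseudo_freq
  out
}

#' Complex-Morlet CWT scalogram image of a padded cycle
#'
#' Magnitudes from [cwt_magnitudes()], log-compressed, min-max normalised and
#' resized to `size x size`. Rows are ordered low to high pseudo-frequency to
#' match the mel branch orientation.
#'
#' @inheritParams cwt_magnitudes
#' @param size Output image side length.
#' @param log_floor Additive floor before the log compression.
#' @return A `lung_scalogram` matrix in \[0, 1\].
#' @export
cwt_scalogram <- function(waveform, params = cwt_params(), sample_rate = 4000,
                          size = 128L, log_floor = 1e-10) {
  mag <- cwt_magnitudes(waveform, params, sample_rate)
  mag <- mag[rev(seq_len(nrow(mag))), , drop = FALSE]   # low freq at row 1
  to_image(mag, size = size, log_floor = log_floor, branch = "cwt")
}
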