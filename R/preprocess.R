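#' Padding configuration
#'
#' Every respiratory cycle is brought to a fixed duration of six seconds at a
#' common 4000 Hz rate before transformation, i.e. 24,000 samples.
#'
#' @param target_duration Seconds (default 6).
#' @param sample_rate Hz (default 4000).
#' @export
pad_config <- function(target_duration = 6, sample_rate = 4000) {
  stopifnot(target_duration > 0, sample_rate > 0)
  list(target_duration = target_duration, sample_rate = sample_rate)
}

#' Augmentation parameters
#'
#' Defaults follow the method's stated settings: time-stretch rate 1.2, pitch
#' shift drawn uniformly within +/-0.2 fractional octaves, additive Gaussian
#' noise scaled by 0.005.
#'
#' @param stretch_rate Output duration as a multiple of the input's.
#' @param pitch_shift_max Bound on the random shift, in fractional octaves.
#' @param noise_scale Amplitude factor on the unit-variance noise vector.
#' @param seed Integer seed for the random draws.
#' @export
augment_params <- function(stretch_rate = 1.2, pitch_shift_max = 0.2,
                           noise_scale = 0.005, seed = 1L) {
  stopifnot(stretch_rate > 0, pitch_shift_max >= 0, noise_scale >= 0)
  list(stretch_rate = stretch_rate, pitch_shift_max = pitch_shift_max,
       noise_scale = noise_scale, seed = as.integer(seed))
}

#' Resample a waveform between integer sampling rates
#'
#' Polyphase resampling (via \pkg{signal}) at the reduced rational ratio;
#' duration is preserved within one sample period.
#'
#' @param waveform Numeric vector.
#' @param from,to Original and target sampling rates in Hz.
#' @return Numeric vector of `round(length(waveform) * to / from)` samples.
#' @export
resample_wave <- function(waveform, from, to) {
  stopifnot(from > 0, to > 0)
  if (from == to) return(waveform)
  g <- gcd(round(to), round(from))
  y <- signal::resample(waveform, round(to) / g, round(from) / g)
  n_out <- round(length(waveform) * to / from)
  fit_length(y, n_out)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

fit_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

#' Pad or truncate a waveform to the fixed cycle length
#'
#' Shorter cycles are right-padded with zeros; cycles longer than the target
#' keep their leading samples (onset content retained). Idempotent.
#'
#' @param waveform Numeric vector at `config$sample_rate`.
#' @param config A [pad_config()].
#' @return Numeric vector of exactly
#'   `round(config$target_duration * config$sample_rate)` samples.
#' @export
pad_or_truncate <- function(waveform, config = pad_config()) {
  if (length(waveform) == 0) stop("cannot pad an empty waveform")
  fit_length(waveform, round(config$target_duration * config$sample_rate))
}

#' Time-stretch a waveform without changing its pitch
#'
#' Phase-vocoder implementation: the short-time spectrum is resampled along
#' the frame axis with phase accumulation, so a rate of 1.2 lengthens the
#' audio to 1.2x its original duration while dominant frequencies stay put.
#'
#' @param waveform Numeric vector.
#' @param rate Positive duration multiplier (1.2 lengthens by 20%).
#' @param n_fft,hop STFT analysis window and hop in samples.
#' @return Numeric vector of `round(rate * length(waveform))` samples.
#' @export
time_stretch <- function(waveform, rate, n_fft = 512, hop = 128) {
  if (rate <= 0) stop("stretch rate must be positive")
  n <- length(waveform)
  if (rate == 1) return(waveform)
  if (n < n_fft) {
    pad <- n_fft - n
    return(fit_length(time_stretch(c(waveform, numeric(pad)), rate, n_fft, hop),
                      round(rate * n)))
  }
  win <- hann_window(n_fft)
  frames <- stft_frames(waveform, win, hop)              # bins x T complex
  T_in <- ncol(frames)
  steps <- seq(0, T_in - 1, by = 1 / rate)
  steps <- steps[steps <= T_in - 1 + 1e-9]
  omega <- 2 * pi * hop * (seq_len(nrow(frames)) - 1) / n_fft

  mag <- Mod(frames); phs <- Arg(frames)
  out <- matrix(0i, nrow(frames), length(steps))
  acc <- phs[, 1]
  for (k in seq_along(steps)) {
    i <- min(floor(steps[k]) + 1, T_in)
    frac <- steps[k] - (i - 1)
    i2 <- min(i + 1, T_in)
    m <- (1 - frac) * mag[, i] + frac * mag[, i2]
    out[, k] <- m * exp(1i * acc)
    dphi <- phs[, i2] - phs[, i] - omega
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))       # principal value
    acc <- acc + omega + dphi
  }
  y <- istft_frames(out, win, hop)
  fit_length(y, round(rate * n))
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# STFT helper: columns are windowed FFT frames at the given hop (no padding).
stft_frames <- function(x, win, hop) {
  n_fft <- length(win)
  starts <- seq(1, length(x) - n_fft + 1, by = hop)
  vapply(starts, function(s) fft(x[s + seq_len(n_fft) - 1] * win),
         complex(n_fft))
}

istft_frames <- function(frames, win, hop) {
  n_fft <- length(win)
  T_out <- ncol(frames)
  n <- (T_out - 1) * hop + n_fft
  y <- numeric(n); wsum <- numeric(n)
  for (k in seq_len(T_out)) {
    idx <- (k - 1) * hop + seq_len(n_fft)
    y[idx] <- y[idx] + win * Re(fft(frames[, k], inverse = TRUE)) / n_fft
    wsum[idx] <- wsum[idx] + win^2
  }
  y / pmax(wsum, 1e-8)
}

#' Pitch-shift a waveform while keeping its duration constant
#'
#' Frequencies are multiplied by `2^u` with `u` drawn uniformly from
#' `[-max_shift, +max_shift]` fractional octaves: the signal is first
#' time-stretched by `2^u` (pitch-preserving) and then resampled back to its
#' original length, which scales all frequencies by `2^u`.
#'
#' @param waveform Numeric vector.
#' @param sample_rate Hz (retained for interface symmetry; the shift is
#'   relative so the rate does not enter the computation).
#' @param max_shift Bound in fractional octaves (>= 0).
#' @param seed Optional integer seed for the uniform draw.
#' @param shift Force a specific shift `u` instead of drawing one.
#' @return Numeric vector of the same length as `waveform`.
#' @export
pitch_shift <- function(waveform, sample_rate = 4000, max_shift = 0.2,
                        seed = NULL, shift = NULL) {
  if (max_shift < 0) stop("max_shift must be non-negative")
  u <- shift %||% {
    draw <- function() runif(1, -max_shift, max_shift)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  if (u == 0) return(waveform)
  n <- length(waveform)
  stretched <- time_stretch(waveform, 2^u)
  resample_to_length(stretched, n)
}

# Resample to an arbitrary length: low-pass (when decimating) then linear
# interpolation on the regular grid.
resample_to_length <- function(x, n_out) {
  if (n_out == length(x)) return(x)
  if (n_out < length(x)) {
    cutoff <- 0.9 * n_out / length(x)
    bf <- signal::butter(6, cutoff, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Add scaled Gaussian noise to a waveform
#'
#' A zero-mean unit-variance noise vector of matching length is scaled by
#' `scale` and added element-wise.
#'
#' @param waveform Numeric vector.
#' @param scale Amplitude factor (default 0.005).
#' @param seed Optional integer seed.
#' @return Numeric vector of the same length.
#' @export
add_noise <- function(waveform, scale = 0.005, seed = NULL) {
  if (scale < 0) stop("noise scale must be non-negative")
  if (scale == 0) return(waveform)
  g <- if (is.null(seed)) rnorm(length(waveform))
       else withr::with_seed(seed, rnorm(length(waveform)))
  waveform + scale * g
}

#' Expand a dataset with per-class augmented copies
#'
#' Each cycle of class `c` gains `multiplicity[c]` augmented copies, the
#' operator cycling round-robin over time stretch, pitch shift and additive
#' noise. Copies inherit all labels and are flagged `augmented = TRUE`.
#'
#' @param cycles A `lung_cycles` tibble.
#' @param params An [augment_params()].
#' @param multiplicity Named non-negative integers per cycle label, e.g.
#'   `c(W = 3, B = 3)`; absent classes get no copies.
#' @return The input tibble with the augmented copies appended.
#' @export
augment_dataset <- function(cycles, params = augment_params(),
                            multiplicity = c(N = 0, C = 0, W = 0, B = 0)) {
  if (any(multiplicity < 0)) stop("multiplicity values must be >= 0")
  mult <- multiplicity[cycles$cycle_label]
  mult[is.na(mult)] <- 0L
  ops <- c("stretch", "pitch", "noise")
  copies <- purrr::map(which(mult > 0), function(r) {
    row <- cycles[r, ]
    purrr::map(seq_len(mult[r]), function(m) {
      op <- ops[(m - 1L) %% 3L + 1L]
      seed_m <- (params$seed + 131L * r + m) %% .Machine$integer.max
      w <- row$waveform[[1]]
      w2 <- switch(op,
        stretch = time_stretch(w, params$stretch_rate),
        pitch   = pitch_shift(w, row$sample_rate, params$pitch_shift_max,
                              seed = seed_m),
        noise   = add_noise(w, params$noise_scale, seed = seed_m))
      out <- row
      out$waveform <- list(w2)
      out$end_time <- out$start_time + length(w2) / out$sample_rate
      out$augmented <- TRUE
      out$recording_id <- paste0(out$recording_id, "-aug", m)
      out
    })
  })
  as_lung_cycles(dplyr::bind_rows(cycles, dplyr::bind_rows(purrr::flatten(copies))))
}

#' Resample and pad all cycles to the fixed-length model input
#'
#' Brings every cycle to `config$sample_rate`, then zero-pads or truncates to
#' `config$target_duration` seconds.
#'
#' @param cycles A `lung_cycles` tibble.
#' @param config A [pad_config()].
#' @return The tibble with `waveform` replaced by fixed-length vectors and
#'   `sample_rate` set to the common rate.
#' @export
preprocess_cycles <- function(cycles, config = pad_config()) {
  cycles$waveform <- purrr::map2(cycles$waveform, cycles$sample_rate, function(w, fs) {
    pad_or_truncate(resample_wave(w, fs, config$sample_rate), config)
  })
  cycles$sample_rate <- config$sample_rate
  as_lung_cycles(cycles)
}
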