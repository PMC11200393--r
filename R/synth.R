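#' Configuration for the synthetic ICBHI-layout generator
#'
#' Defaults emulate the source database's published composition: cycle-label
#' probabilities proportional to the 3642/1864/886/506 N/C/W/B counts and
#' disease probabilities proportional to the per-disease cycle counts of the
#' eight-class vocabulary. Breath noise is band-limited Gaussian noise with an
#' inspiration/expiration envelope; crackle and wheeze events ride on top of
#' it at `snr_db` decibels above the breath floor in their own band.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines the generated dataset.
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param n_patients Number of synthetic patients.
#' @param cycles_per_recording Respiratory cycles per recording.
#' @param class_mix Named probabilities over `c(N, C, W, B)`.
#' @param disease_mix Named probabilities over the 8 disease labels.
#' @param snr_db Event-to-breath-noise ratio in dB within the event band.
#' @param duration_range Cycle duration bounds in seconds.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         sample_rate = 4000,
                         n_patients = 10L,
                         cycles_per_recording = 8L,
                         class_mix = c(N = 3642, C = 1864, W = 886, B = 506) / 6898,
                         disease_mix = c(Healthy = 322, Pneumonia = 285, LRTI = 32,
                                         Asthma = 6, Bronchiectasis = 104, URTI = 243,
                                         Bronchiolitis = 160, COPD = 3642) / 4794,
                         snr_db = 10,
                         duration_range = c(0.5, 6)) {
  stopifnot(sample_rate > 0, n_patients >= 1, cycles_per_recording >= 1,
            duration_range[1] > 0, duration_range[2] >= duration_range[1])
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (abs(sum(disease_mix) - 1) > 1e-9) stop("disease_mix must sum to 1")
  if (!setequal(names(class_mix), CYCLE_LEVELS)) stop("class_mix needs names N,C,W,B")
  if (!setequal(names(disease_mix), DISEASE_LEVELS))
    stop("disease_mix needs the 8 disease names")
  structure(list(seed = as.integer(seed), sample_rate = sample_rate,
                 n_patients = as.integer(n_patients),
                 cycles_per_recording = as.integer(cycles_per_recording),
                 class_mix = class_mix[CYCLE_LEVELS],
                 disease_mix = disease_mix[DISEASE_LEVELS],
                 snr_db = snr_db, duration_range = duration_range),
            class = "synth_config")
}

raised_cosine_env <- function(n, frac = 0.1) {
  # flat-topped envelope with raised-cosine onset and offset ramps
  m <- max(2L, round(n * frac))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  env <- rep(1, n)
  env[seq_len(m)] <- ramp
  env[n - m + seq_len(m)] <- rev(ramp)
  env
}

#' Generate one synthetic wheeze
#'
#' A wheeze is a continuous, high-pitched adventitious sound, typically
#' 400--500 Hz and longer than 100 ms: modelled as an amplitude-enveloped
#' sinusoid with raised-cosine onset and offset.
#'
#' @param duration Seconds; must exceed 0.1 s.
#' @param freq Tone frequency in Hz (default policy requires 400--500 Hz).
#' @param sample_rate Hz.
#' @param amplitude Peak amplitude scale.
#' @return Numeric amplitude vector of `round(duration * sample_rate)` samples.
#' @export
synth_wheeze <- function(duration, freq = 450, sample_rate = 4000, amplitude = 1) {
  if (duration <= 0.1)
    stop("a wheeze must last longer than 100 ms (got ", duration, " s)")
  if (freq < 400 || freq > 500)
    stop("wheeze frequency must lie in 400-500 Hz (got ", freq, " Hz)")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  amplitude * raised_cosine_env(n) * sin(2 * pi * freq * t + runif(1, 0, 2 * pi))
}

#' Generate one synthetic crackle
#'
#' A crackle is a discontinuous, short (here <= 20 ms) transient with a pitch
#' between 100 and 2000 Hz: modelled as an exponentially damped oscillation.
#'
#' @param sample_rate Hz.
#' @param center_freq Oscillation frequency, 100--2000 Hz.
#' @param amplitude Peak amplitude scale.
#' @return Numeric amplitude vector (<= 20 ms of samples).
#' @export
synth_crackle <- function(sample_rate = 4000, center_freq = 800, amplitude = 1) {
  if (center_freq < 100 || center_freq > 2000)
    stop("crackle pitch must lie in 100-2000 Hz (got ", center_freq, " Hz)")
  dur <- 0.016                                    # 16 ms burst
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  amplitude * exp(-t / 0.003) * sin(2 * pi * center_freq * t)
}

#' Generate band-limited breath noise
#'
#' Gaussian noise band-passed to the auscultation band (50--2500 Hz, upper
#' edge clipped below Nyquist) and shaped by a two-lobe raised-cosine
#' inspiration/expiration envelope.
#'
#' @param n_samples Length in samples.
#' @param sample_rate Hz.
#' @param band Passband in Hz.
#' @param rms Target root-mean-square amplitude of the unenveloped noise.
#' @return Numeric amplitude vector.
#' @export
synth_breath_noise <- function(n_samples, sample_rate = 4000,
                               band = c(50, 2500), rms = 0.05) {
  hi <- min(band[2], 0.95 * sample_rate / 2)
  bf <- signal::butter(4, c(band[1], hi) / (sample_rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n_samples))
  x <- x / sd(x) * rms
  u <- seq(0, 1, length.out = n_samples)
  lobe <- function(c0, c1, h) ifelse(u >= c0 & u <= c1,
                                     h * 0.5 * (1 - cos(2 * pi * (u - c0) / (c1 - c0))),
                                     0)
  env <- 0.25 + lobe(0.02, 0.45, 1) + lobe(0.5, 0.98, 0.75)
  x * env
}

band_rms <- function(x, sample_rate, band) {
  bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
  sqrt(mean(signal::filtfilt(bf, x)^2))
}

#' Generate one labelled synthetic respiratory cycle
#'
#' Breath noise plus, per label: `C` adds at least three crackle transients,
#' `W` at least one wheeze tone, `B` both, `N` neither. Events are placed
#' uniformly at random inside the central 90% of the cycle, at
#' `config$snr_db` dB above the breath floor in their own frequency band.
#' Draws come from the current RNG state; wrap in [withr::with_seed()] (as
#' [synth_cycles()] and [synth_dataset()] do) for reproducibility.
#'
#' @param label One of `"N"`, `"C"`, `"W"`, `"B"`.
#' @param config A [synth_config()].
#' @param duration Optional fixed duration in seconds; drawn uniformly from
#'   `config$duration_range` when `NULL`.
#' @return Numeric amplitude vector with attributes `label` and `sample_rate`.
#' @export
synth_cycle <- function(label, config = synth_config(), duration = NULL) {
  label <- match.arg(label, CYCLE_LEVELS)
  fs <- config$sample_rate
  if (is.null(duration))
    duration <- runif(1, config$duration_range[1], config$duration_range[2])
  n <- round(duration * fs)
  x <- synth_breath_noise(n, fs)
  gain <- 10^(config$snr_db / 20)

  place <- function(event) {
    lo <- round(0.05 * n); hi <- n - round(0.05 * n) - length(event)
    if (hi <= lo) return(NULL)
    at <- sample(lo:hi, 1)
    idx <- at + seq_along(event)
    x[idx] <<- x[idx] + event
    invisible(NULL)
  }
  if (label %in% c("W", "B")) {
    n_wheezes <- sample(1:2, 1)
    for (k in seq_len(n_wheezes)) {
      f <- runif(1, 400, 500)
      # wheezes are sustained: a sizeable fraction of the breath phase
      d <- max(0.15, min(runif(1, 0.25, 0.6) * duration, 2.5))
      amp <- sqrt(2) * band_rms(x, fs, c(400, 500)) * gain
      place(synth_wheeze(d, f, fs, amplitude = amp))
    }
  }
  if (label %in% c("C", "B")) {
    n_crackles <- sample(3:8, 1)
    for (k in seq_len(n_crackles)) {
      f <- runif(1, 150, 1800)
      amp <- 3 * sd(x) * gain
      place(synth_crackle(fs, f, amplitude = amp))
    }
  }
  x <- x / max(1, max(abs(x)) / 0.99)              # keep nominal [-1, 1]
  structure(x, label = label, sample_rate = fs)
}

#' Generate a tibble of synthetic cycles with exact per-class counts
#'
#' Convenience for balanced experiments: produces `n_per_class` cycles for
#' each requested label, already in the [segment_cycles()] tibble layout.
#'
#' @param n_per_class Cycles per label.
#' @param config A [synth_config()]; `config$seed` seeds the draw.
#' @param labels Which labels to generate.
#' @return A `lung_cycles` tibble.
#' @export
synth_cycles <- function(n_per_class, config = synth_config(),
                         labels = CYCLE_LEVELS) {
  withr::with_seed(config$seed, {
    rows <- purrr::map(labels, function(lab) {
      purrr::map(seq_len(n_per_class), function(i) {
        w <- synth_cycle(lab, config)
        tibble::tibble(patient_id = sprintf("s%s%03d", lab, i),
                       recording_id = sprintf("s%s%03d_r1", lab, i),
                       cycle_index = 1L,
                       start_time = 0,
                       end_time = length(w) / config$sample_rate,
                       crackles = as.integer(lab %in% c("C", "B")),
                       wheezes  = as.integer(lab %in% c("W", "B")),
                       cycle_label = lab,
                       disease_label = NA_character_,
                       sample_rate = config$sample_rate,
                       augmented = FALSE,
                       waveform = list(as.numeric(w)))
      })
    })
    as_lung_cycles(dplyr::bind_rows(purrr::flatten(rows)))
  })
}

#' Write a synthetic dataset in the ICBHI layout
#'
#' Emits one WAV + annotation pair per recording plus a `diagnosis.csv`, all
#' readable back through [load_dataset()] with no skips. Each patient draws a
#' disease from `config$disease_mix`; `Healthy` patients produce all-normal
#' recordings, every other patient draws cycle labels from `config$class_mix`.
#'
#' @param config A [synth_config()].
#' @param out_root Output directory (created if needed).
#' @return The manifest tibble (`recording_id`, `patient_id`, `disease`,
#'   `n_cycles`), invisibly; files land under `out_root`.
#' @export
synth_dataset <- function(config = synth_config(), out_root) {
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    manifest <- purrr::map(seq_len(config$n_patients), function(p) {
      pid <- sprintf("%03d", 100L + p)
      disease <- sample(DISEASE_LEVELS, 1, prob = config$disease_mix)
      labels <- if (disease == "Healthy") rep("N", config$cycles_per_recording)
                else sample(CYCLE_LEVELS, config$cycles_per_recording,
                            replace = TRUE, prob = config$class_mix)
      # quantize durations to whole milliseconds so the 3-decimal annotation
      # times reproduce the sample boundaries exactly on read-back
      durations <- round(runif(length(labels), config$duration_range[1],
                               config$duration_range[2]), 3)
      cycles <- purrr::map2(labels, durations, function(lab, d)
        synth_cycle(lab, config, duration = d))
      ends <- floor(cumsum(vapply(cycles, length, 1L)) / config$sample_rate * 1000 +
                      1e-6) / 1000
      ann <- tibble::tibble(start_time = c(0, head(ends, -1)), end_time = ends,
                            crackles = as.integer(labels %in% c("C", "B")),
                            wheezes  = as.integer(labels %in% c("W", "B")))
      stem <- sprintf("%s_r1", pid)
      write_wav(unlist(cycles), config$sample_rate,
                file.path(out_root, paste0(stem, ".wav")))
      write_annotation_file(ann, file.path(out_root, paste0(stem, ".txt")))
      tibble::tibble(recording_id = stem, patient_id = pid, disease = disease,
                     n_cycles = length(labels))
    })
    manifest <- dplyr::bind_rows(manifest)
    write.csv(manifest[, c("patient_id", "disease")],
              file.path(out_root, "diagnosis.csv"), row.names = FALSE, quote = FALSE)
    invisible(manifest)
  })
}
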