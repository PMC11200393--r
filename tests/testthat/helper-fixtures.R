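# Shared fixtures for the test suite. Everything is generated in code from
# fixed seeds; nothing is read from disk except the bundled example
# annotation file.

make_tone <- function(freq, duration = 1, sample_rate = 4000, amp = 0.5) {
  amp * sin(2 * pi * freq * (seq_len(round(duration * sample_rate)) - 1) / sample_rate)
}

fft_peak_hz <- function(x, sample_rate) {
  n <- length(x)
  spec <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  (which.max(spec) - 1) * sample_rate / n
}

example_annotation_path <- function() {
  system.file("extdata", "example_annotation.txt", package = "lungsound")
}

# A small, quick synthetic configuration used across tests.
tiny_config <- function(seed = 1L, duration_range = c(0.5, 2), ...) {
  synth_config(seed = seed, n_patients = 4L, cycles_per_recording = 5L,
               duration_range = duration_range, ...)
}
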