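---
title: "Classifying respiratory sounds with parallel scalograms, autoencoder fusion and an LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying respiratory sounds with parallel scalograms, autoencoder fusion and an LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungsound)
```

## The problem

Lung auscultation classifies breath sounds into normal cycles and cycles
carrying adventitious events: *crackles* (discontinuous transients, pitch
roughly 100–2000 Hz, under ~20 ms) and *wheezes* (continuous high-pitched
tones, typically 400–500 Hz, longer than 100 ms). Manual interpretation is
subjective and error-prone, which motivates automated classification of
recorded respiratory cycles. This package implements a hybrid
signal-processing / deep-learning pipeline for that task:

1. recordings in the ICBHI-2017 layout (WAV + per-cycle annotations + a
   per-patient diagnosis table) are segmented into labelled respiratory
   cycles (N / C / W / B, for normal, crackle, wheeze, both);
2. each cycle is resampled to 4000 Hz and zero-padded (or truncated) to a
   fixed six-second window — 24,000 samples;
3. the cycle is transformed **in parallel** into two 128×128
   time–frequency images: a log-mel spectrogram and a complex-Morlet
   continuous-wavelet-transform (CWT) scalogram;
4. one convolutional autoencoder (CAE) per branch compresses its image into
   a 2048-dimensional latent vector; the two latents are concatenated into
   a 4096-dimensional *hybrid feature pool*, reshaped to an 8×512 sequence;
5. a single-layer, 64-unit LSTM with a softmax head classifies the
   sequence into the task's classes (binary, three-, four- or eight-class
   menus).

## Model components and their parameters

### Segmentation and padding

Cycle *k* of a recording occupies the half-open sample interval
`[round(start·fs), round(end·fs))`; half-open intervals make gapless
annotations partition the signal without duplicated boundary samples.
All cycles are brought to 4000 Hz (`pad_config()`'s default), the lowest
rate used by the recording devices, and padded with trailing zeros to 6 s.
Cycles longer than 6 s keep their leading samples: onsets carry most of the
diagnostic content and a fixed input size is required by the convolutional
encoder. Padding is idempotent by construction.

### Augmentation operators

Three time-domain operators expand minority classes
(`augment_dataset()`, applied round-robin per copy):

* **time stretch** (`time_stretch()`, default rate 1.2) — a phase vocoder
  resamples the short-time spectrum along the frame axis with phase
  accumulation, so duration scales by the rate while pitch is unchanged;
* **pitch shift** (`pitch_shift()`, default bound ±0.2 fractional octaves)
  — frequencies are multiplied by `2^u`, `u ~ U(−0.2, 0.2)`, by stretching
  `2^u` and resampling back to the original length. The bound is read as
  fractional octaves; the alternative reading (a time-axis shift) would be
  a no-op for a classifier and contradicts "changes the audio's frequency
  content", so it was rejected;
* **additive noise** (`add_noise()`, default scale 0.005) — a unit-variance
  Gaussian vector of matching length scaled and added element-wise.

Augmentation is applied after the train/test split, to the training
portion only; augmenting first would leak near-copies of test cycles into
training. The per-class multiplicities are fully configurable because the
published per-class totals are not integer multiples of the originals.

### Time–frequency branches

Neither STFT nor CWT discretisation constants are fixed by the method's
description, so they are package defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| STFT window / hop | Hann 512 / 128 samples | 128 ms windows at 4 kHz; a 6 s cycle yields 184 frames ≥ 128 |
| mel bands | 128 over 25–2000 Hz | one band per image row; 2000 Hz is Nyquist |
| CWT scales | 128, geometric | pseudo-frequencies span 25–2000 Hz |
| Morlet parameters | centre frequency 1.0, bandwidth 1.5 | standard complex-Morlet shape; centre 1.0 keeps scales `s = fs/f` |
| translation step | 128 samples, 4× oversampled and max-pooled | matches the STFT hop; 188 columns per cycle |

The CWT magnitudes are evaluated at four translations per step and
max-pooled within each step: the wavelet at high pseudo-frequencies has a
support of only a few milliseconds, so a point-sampled translation grid
can miss a 16 ms crackle entirely. (The overlapping 512-sample STFT
window integrates transients by itself, so the mel branch needs no
analogous pooling; hop variants that avoid the time-axis resize were
tried during development and generalised slightly worse than the
smoothing bilinear resize.)

The CWT is evaluated in the frequency domain using the Morlet's
closed-form Gaussian spectrum, with zero-padding past the wavelet support;
a decimation-by-spectrum-folding step returns exactly the hopped
translations. The implementation is validated against a direct Riemann-sum
evaluation on short signals (relative error below 1e-3; in practice ~1e-8).

Images are rendered by `to_image()`: decibel compression (10 dB/decade for
the power-quantity mel grid, 20 dB/decade for CWT magnitudes, additive
floor 1e-10), clipping to the top 60 dB below the per-image maximum,
min-max normalisation to [0, 1], and bilinear resize to 128×128. The 60 dB
clip matters: the zero-padded region otherwise anchors the minimum some
230 dB below the signal and compresses all in-signal contrast (crackle and
wheeze marks included) into a few percent of the intensity range. A
constant grid maps to an all-0.5 image so downstream stages always receive
well-defined input.

### Convolutional autoencoders

Each branch has its own CAE: five 3×3, stride-2 convolutions with ReLU
(1→16→32→64→128→128 channels, 128×128 → 4×4) flattened to a 2048-long
latent; the decoder mirrors it (dense 2048→2048, reshape to 4×4×128, five
3×3 stride-2 transposed convolutions, ReLU except a sigmoid output).
3×3/stride-2 is the minimal kernel choice reproducing every printed stage
shape. Training minimises mean squared reconstruction error with Adam
(learning rate 0.001, β₁ 0.9, β₂ 0.999, batch 32). The CAEs are trained
unsupervised on **training images only** and frozen before classifier
training (two-phase); reconstruction quality is reported as PSNR
(`psnr()`, `10·log10(1/MSE)`, capped at 120 dB for exact matches).

The fused 4096-vector is reshaped row-major into 8 timesteps × 512
features: 512 is the unique input width for which a 64-unit LSTM has the
printed 147,712 parameters, and 8 = 4096/512 follows. Single-branch
ablations reshape one 2048-latent to 4×512 with the same convention.

Before sequencing, latent features are standardised with training-set
means and standard deviations. The ReLU latents are non-negative with
magnitudes around 5–10; fed raw into sigmoid/tanh gates they saturate the
LSTM and gradient flow collapses (training accuracy stays at chance).
Standardisation is fitted on the training partition only and applied to
both partitions.

### LSTM classifier

A single LSTM layer (64 units; input, forget, cell and output gates with
sigmoid/tanh activations, forget-gate bias initialised to 1) reads the
sequence; the final hidden state feeds a dense softmax. Training uses
categorical cross-entropy with Adam at learning rate 0.001 — the setting
reported to score best over 200 epochs — with every random draw
(initialisation, shuffling) tied to an integer seed. For the fused input
and two classes the parameter count is exactly
`4·((512+64)·64+64) + (64·2+2) = 147,842`.

## Evaluation

`task_definition()` provides the task menu: `n-ab` (normal vs all
adventitious), the label-pair binaries (`c-w`, `b-c`, `b-w`, `c-n`,
`w-n`), two three-class tasks (`b-c-w`, `c-n-w`), the four-class N/C/W/B
task, and the eight-class disease task driven by the diagnosis table.
Splitting is stratified per class at 80/20 and per cycle, matching the
study's accounting; note that per-cycle splitting lets cycles of one
patient appear on both sides — an acknowledged caveat of that protocol
(`split_dataset()` stratifies on whatever label column you give it, so a
patient-level split can be emulated by splitting a patient table first).

Metrics are one-vs-rest: accuracy, precision, sensitivity, specificity
and F1 per class (`tidy()` on a confusion matrix), macro-averaged
(unweighted class mean) by default with micro also emitted
(`metrics()`). The averaging mode of the published single "average"
values is unstated; macro was chosen because the reported specificity far
exceeds the reported accuracy, which is characteristic of macro one-vs-rest
averaging on imbalanced classes. F1 uses the 0/0 → 0 convention.

## The synthetic data generator

Real auscultation data cannot be bundled, so `synth_cycles()` /
`synth_dataset()` generate ICBHI-layout datasets whose acoustic structure
matches the field's sound definitions:

* breath noise: Gaussian noise band-passed 50–2500 Hz (upper edge clipped
  below Nyquist) under a two-lobe raised-cosine inspiration/expiration
  envelope with a 0.25 baseline;
* wheezes: raised-cosine-enveloped sinusoids at 400–500 Hz, sustained for
  25–60% of the cycle (at least 150 ms, at most 2.5 s) — wheezes occupy a
  sizeable fraction of the breath phase;
* crackles: 16 ms exponentially damped oscillations at 150–1800 Hz, at
  least three per crackle-labelled cycle;
* events sit `snr_db` (default 10 dB) above the breath floor within their
  own band, and are placed uniformly inside the central 90% of the cycle;
* default label and disease mixes follow the source database's published
  proportions; `Healthy` patients emit all-normal recordings, and cycle
  durations are drawn from 0.5–6 s (quantised to milliseconds so written
  annotations round-trip exactly).

At these defaults a trivial 400–500 Hz band-energy threshold separates N
from W cycles with ≥95% accuracy, so the end-to-end pipeline demonstrably
has signal to learn. What the generator does *not* emulate: device and
chest-wall transfer functions, heart sounds and friction artefacts,
patient-correlated cycle structure, and the heavy class imbalance noise of
clinical data. Green synthetic tests therefore certify the pipeline's
mechanics and learnability, not clinical performance.

## Numerical choices and degenerate inputs

* Conv/transposed-conv layers run as im2col + GEMM kernels (RcppArmadillo)
  in single precision inside the layer, with double-precision parameters
  and a double-precision Adam update; a layer-by-layer double-precision R
  path computes the same forward/backward quantities and the test suite
  asserts agreement (loss to 1e-6, gradients to 1e-4 relative).
* Stride-2 "same" padding is asymmetric (0 leading, 1 trailing), the
  convention under which 128 → 64 → … → 4 exactly.
* `psnr()` returns the 120 dB cap for identical images; `to_image()` maps
  constant grids to 0.5; empty waveforms, too-short STFT inputs,
  out-of-band event frequencies, single-class training sets and
  annotation rows violating `end > start ≥ 0` all raise errors naming the
  offending input.
* Every stochastic step (generator, initialisation, shuffling, splits,
  augmentation draws) is driven by explicit integer seeds; sub-seeds are
  derived deterministically from the master seed.

## Desk-scale problem sizes

The bundled experiments run on one CPU: the four-class synthetic study
uses 200 cycles per class (640 training / 160 test after the 80/20
split), 30 CAE epochs and 50 LSTM epochs; the test suite's unit fixtures
are far smaller. These sizes are the package's reference conditions for
the reproducibility checks in `scripts/acceptance.R`; larger runs only
require raising the epoch counts and cycle counts in the calls.

## Known limitations

* The published headline accuracies on ICBHI-2017 depend on that dataset
  (not redistributable here), unpublished splits and long GPU training;
  they are out of the package's verification scope. The package verifies
  the architecture identities exactly and the method's behaviour on
  seeded synthetic data, including the directional ablation finding that
  fused features match or beat either single branch.
* The CWT uses one wavelet family (complex Morlet) by design; no other
  families are provided.
* Metrics average modes beyond macro/micro (e.g. frequency-weighted) are
  not implemented.
* The eight-class synthetic task is honest only through the diagnosis
  table join: by default disease labels are independent of the audio, so
  a classifier should *not* beat chance there — this is deliberate, to
  avoid manufacturing fake disease separability.
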