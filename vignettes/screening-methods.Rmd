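---
title: "Heart-failure screening from heart sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-failure screening from heart sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcgscreen)
```

## The screening problem

Heart failure alters the mechanical activity of the heart, and with it the
acoustics of the first and second heart sounds (S1, S2) captured in a
phonocardiogram (PCG). `pcgscreen` implements a three-class screening
pipeline — normal, heart failure with preserved ejection fraction (HFpEF),
and with reduced ejection fraction (HFrEF) — that goes from raw PCG audio to
a cross-validated classifier report:

1. resample to a 600 Hz working rate,
2. localize S1 onsets with a duration-dependent hidden semi-Markov model,
3. cut fixed-length frames anchored at successive S1 onsets
   (period-synchronous framing) and min-max normalize each frame,
4. classify frames with a gated recurrent network (GRU; LSTM, a fully
   convolutional network and a feature+SVM baseline are provided for
   comparison),
5. evaluate by stratified tenfold cross-validation.

Because clinical HF recordings are not publicly available, the package ships
a synthetic PCG generator with exact ground-truth S1/S2 onsets and state
paths, so every stage is testable end to end without downloads.

## The synthetic generator — what it emulates and what it does not

Each cardiac cycle is two Gaussian-windowed band-limited chirp transients:
S1 at the cycle start with spectral energy inside 10–200 Hz, and S2 at the
end of systole inside 20–250 Hz. Cycle durations are drawn uniformly and
independently from 0.6–0.8 s, the typical cardiac period. Defaults: S1
lasts 0.12 s, S2 0.10 s, the S1→S2 (systolic) interval is 42% of the cycle,
and white Gaussian noise is added at 25 dB SNR — physiologically plausible
values we fixed once when designing the generator.

The three class profiles are *acoustic surrogates*, not clinical models: the
HFpEF profile accentuates S2 (+25%), widens its band and adds a soft
systolic murmur; the HFrEF profile attenuates S1 to 55% (reduced
contractility), widens its band and adds low-frequency baseline content.
No quantitative acoustic differences between the clinical classes are
published for this task, so these effect sizes are free design parameters.
Consequently, a passing end-to-end test shows that the pipeline can learn
class-conditional acoustic structure that survives per-frame min-max
normalization; it does not certify clinical accuracy on real HF patients.
Real PCG features the generator does not emulate: S3/S4 gallops, genuine
murmur taxonomies, sensor and contact noise, inter-subject variability of
the spectral envelope.

## Segmentation: the duration-dependent HSMM

A cardiac period is modelled as the cyclic state sequence
S1 → systole → S2 → diastole. The segmenter has three parts:

* **Envelope features** at 50 ticks/s: a homomorphic envelope (low-pass on
  the log analytic-signal magnitude, floored at $10^{-4}$ of its maximum so
  silence does not dominate the log range), the Hilbert envelope, and the
  envelope of a 25–120 Hz band-passed copy. Each channel is min-max scaled
  per recording.
* **Emissions**: one-vs-rest logistic regressions per state, fitted on
  synthetic recordings with known state paths and renormalized to per-tick
  posteriors. Note that systole and diastole are both near-silent, so
  instantaneous envelopes cannot fully separate them — the duration model
  carries that distinction.
* **Decoding**: an extended Viterbi over state *visits* with explicit
  duration distributions — truncated discretized Gaussians in ticks, means
  tied to the estimated cycle length (autocorrelation peak of the
  homomorphic envelope within 0.5–1.0 s) via fixed per-state fractions, sd
  20% of the mean, support clipped to mean ± 3 sd and at least one tick.

Numerical conventions, fixed so decoding is exactly reproducible: interior
visits are scored by the duration pmf; the first and last visits may be
truncated and are scored by the survivor function $P(D \ge d)$ (a
single-visit path is scored by the survivor function once); the initial
state carries a uniform 1/4 prior; ties break toward the shorter duration,
then the earlier state in cyclic order. The test suite proves the decoder
equal to an exhaustive enumeration oracle on small random instances.

## Framing and normalization

Frames start at the S1-onset sample (`floor(onset × rate)`, 0-based,
half-open) and span exactly `round(frame_length × rate)` samples — 960 at
the default 1.6 s × 600 Hz, about two cardiac cycles, so consecutive frames
overlap by `frame_length − cycle_length`. The 0.8 s alternative
(one cycle, no overlap) is a first-class option and
`compare_frame_lengths()` runs the paired comparison. Tail frames that
would overrun the recording are dropped, not padded: padding would distort
the min-max normalization
$X = (x - x_{\min})/(x_{\max} - x_{\min})$,
which is applied per frame (a frame is the classifier's input unit, and
per-frame scaling removes amplitude differences between acquisition sites).
A constant frame maps to all zeros rather than dividing by zero.

## The classifiers

The GRU follows the printed cell equations exactly, including the
convention that the update gate multiplies the *previous* state:
$h^{(t)} = z^{(t)} h^{(t-1)} + (1-z^{(t)})\,\tilde h^{(t)}$ — many
libraries use the complementary convention, so the package documents and
tests this one. The LSTM likewise keeps the printed form in which the cell
candidate is squashed by the sigmoid; the common tanh variant is available
via `lstm_candidate = "tanh"`. The default architecture is two recurrent
layers of 64 units feeding a 3-unit softmax head; training minimizes
softmax cross-entropy plus $\lambda \sum w^2$ over weight matrices only
(biases are exempt, the usual practice) with Adam at learning rate 0.001,
$\lambda = 10^{-4}$, batch size 64. Weights start uniform scaled by fan-in
under a fixed seed; hidden states start at zero. The FCN comparison model
is three convolution blocks (128/256/128 filters, kernels 8/5/3, "same"
padding, stride 1, no conv bias) each followed by batch normalization
(momentum 0.9, epsilon $10^{-5}$) and ReLU, then global average pooling.
Forward/backward passes are verified against finite differences, and the
single-step cells against naive equation-level evaluators, to $10^{-12}$.

Two feeding modes exist for the recurrent models: one scalar sample per
timestep (the default, 960 steps per 1.6 s frame) and chunked input
(`input_chunk = k` feeds $960/k$ steps of $k$ samples). Chunking shortens
the unrolled sequence, which both speeds computation and improves gradient
flow; whether the original screening study fed scalars or chunks is not
determinable from its description, so both are supported.

## Feature baseline

The hand-crafted bank is a documented generic set (energies, S1/S2 band
ratio, zero-crossing rate, spectral centroid/bandwidth/rolloff, sample
entropy, octave-band fractions, short-time energy statistics). Screening
uses Tamhane's T2: all pairwise Welch $t$ comparisons across the three
classes with a Šidák-style adjustment $p_{adj} = 1-(1-p)^3$; a feature
passes at adjusted $P < 0.001$, and at most three features are kept (ranked
by smallest adjusted $P$) to mirror the three-feature SVM baseline
protocol. The SVM is one-vs-one RBF with a grid search over
$C \in 2^{\{-5,\dots,15\}}$, $\gamma \in 2^{\{-15,\dots,3\}}$ (step 4 in
the exponent) scored by an internal seeded 3-fold split of the training
rows only; features are standardized with training-fold statistics, so no
information leaks from test folds.

## Evaluation protocol

Tenfold cross-validation, stratified at the frame level: 90% of frames
train, 10% test, and a stratified 20% of each training fold is held out for
validation monitoring (no early stopping — models train for the full epoch
budget). Frame-level splitting mirrors the screening protocol but lets
frames of one recording appear on both sides of a split; the
`grouping = "recording"` mode assigns whole recordings to folds for a
leakage-free variant, and the harness asserts train/validation/test
disjointness on every run. The pooled confusion matrix has true classes in
rows; precision is the column-wise and recall the row-wise diagonal
fraction; fold-accuracy dispersion uses the $n-1$ denominator.

## Problem sizes and epoch budgets

The synthetic study conditions are 10 recordings per class × 25 cycles at
25 dB SNR, about 660 frames of 960 samples — a desk-scale stand-in for the
original ~23,000-frame corpus. At this size one epoch is ~9 mini-batches,
so 50 epochs would be ~450 Adam steps, two orders of magnitude fewer
optimization steps than the same recipe at corpus scale; the end-to-end
evaluation therefore trains for 100 epochs with chunked input
(`input_chunk = 16`, i.e. 60 steps × 16 samples), which reaches a stable
optimum in a few minutes per fold on one core. The architecture, loss,
optimizer, learning rate, $\lambda$ and batch size are unchanged.

## Known limitations

* Surrogate class profiles: effect sizes are design choices, not estimates.
* Emission models are trained on synthetic state paths; a hand-segmented
  corpus would be needed before applying the segmenter clinically.
* Frame-level cross-validation can leak recording identity (see above).
* The sample-entropy feature subsamples frames ×4 for speed.
* `estimate_heart_rate()` reports the dominant tempo; recordings with two
  interleaved rhythms resolve to the stronger autocorrelation peak.
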