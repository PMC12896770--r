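---
title: "Methods: a Mel-spectrogram CNN pipeline for DDK-based PD detection"
author: "ddkcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Mel-spectrogram CNN pipeline for DDK-based PD detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hypokinetic dysarthria — the motor speech disorder typical of Parkinson's
disease (PD) — degrades the rapid syllable repetition (diadochokinesis, DDK)
used clinically to probe articulatory motor control: syllable rates drop,
timing becomes irregular, amplitude modulation flattens, and voice quality
becomes noisier. `ddkcnn` implements a complete pipeline that turns DDK
recordings into fixed-size log-Mel spectrogram excerpts, optionally enriches
the training set with waveform- and spectrogram-level augmentation, trains a
small 2D convolutional network to separate PD from healthy-control (HC)
speech, and evaluates it under subject-independent protocols.

Clinical DDK corpora are access-restricted, so the package ships a seeded
synthetic cohort generator that emulates the relevant signal structure. All
statistical claims made by the test suite are claims about that generator,
not about clinical speech; the pipeline itself consumes any WAV + manifest
cohort in the same format.

## The frontend

Recordings are peak-normalized (loudness carries no diagnostic information
and peak scaling keeps 16-bit I/O exact), downmixed to mono by channel mean,
and resampled to 16 kHz by polyphase band-limited interpolation. Each
recording is cut into 160 ms windows (2560 samples) with 50 % overlap
(hop 1280); incomplete tail windows are dropped rather than zero-padded so
that every excerpt honours the fixed input contract of the network. A
recording of $n$ samples therefore yields
$\lfloor (n-2560)/1280 \rfloor + 1$ segments.

Each segment becomes an 80-band log-Mel matrix: STFT with a 256-sample
periodic Hann window, hop 64, centered (reflect-padded) framing — giving
exactly $1 + \lfloor 2560/64 \rfloor = 41$ frames — power spectra projected
onto a Slaney-style, area-normalized mel filterbank spanning 0–8000 Hz, and
conversion to dB via $10\log_{10}$ referenced to the per-segment maximum
with a floor at −80 dB. Four of these choices (Hann window, centered
framing, power rather than magnitude spectra, per-segment max reference) are
conventions rather than constraints inherited from the task; centered
framing is the one that produces the 41-frame geometry the architecture
expects, and max-referencing makes the representation exactly invariant to
positive rescaling of the input, which the test suite checks bit-for-bit.
The 80 × 41 geometry, 16 kHz rate, and window constants are deliberately not
configurable: they are asserted constants (`ddk_constants()`), because the
network's flatten dimension depends on them.

With 80 triangular filters over 129 FFT bins the low-frequency filters are
narrower than one bin; Slaney area normalization keeps their weights finite,
and a filter that happens to cover no bin would simply contribute floor
values.

## Augmentation operators

Two operators act on waveforms before the frontend:

* **Additive noise** $x'(t) = x(t) + \alpha n(t)$ with $n$ i.i.d. standard
  Gaussian. Waveforms are peak-normalized, so $\alpha$ is a fraction of peak
  amplitude; the default 0.05 puts the noise roughly 26 dB below a
  unit-power signal.
* **Time shift** $x'(t) = x(t-\tau)$, $\tau$ = `tau_fraction` × length,
  implemented circularly so no content is lost and no padding artifact is
  introduced.

Five act on the 80 × 41 matrices: SpecAugment stripes (axis-spanning time
and frequency masks with widths uniform on $\{0,\dots,\max\}$), RandMasking
(several random rectangles), RandMix (rectangles replaced by the aligned
cells of another sample), Cutting Masking (one contiguous region
cut-and-pasted from another sample), and Mixture Masking (one region blended
as $\lambda\,T + (1-\lambda)\,S$). Mask fills default to the −80 dB floor,
with the matrix mean as an alternative. Operator magnitudes have no
canonical values for this task; the defaults (one ≤ 8-frame and one
≤ 12-band SpecAugment stripe, three ≤ 16 × 10 RandMasking blocks, a cut /
mix region drawn up to the full extent with expected area ≈ 26 %) are
package choices, exposed in `aug_config()`.

Three policies are fixed by design. Block sources are always drawn from
*same-class* items, and labels are never mixed — the augmentation is
class-symmetric with hard labels. `expand_training_set()` always doubles the
set (originals plus exactly one augmented copy each), preserving class
balance. And augmentation is applied to training partitions only; each
copy's `source_subject` is recorded so the leakage guards can audit that no
validation or test subject ever contributes pixels to training data. The
"waveform combo" preset composes additive noise and time shift, and is also
available as each operator alone.

## The network

The classifier is a deliberately small CNN over a 1 × 80 × 41 input:
$n \in \{2,\dots,5\}$ blocks of (3 × 3 convolution, padding 1 → ReLU →
2 × 2 max pooling with floor division), channels $1 \to 4 \to 8 \to 16 \to
32 \to 64$ (doubling, truncated at the chosen depth), followed by fully
connected layers $d \to 128 \to 64 \to 2$ with ReLU after the first two.
For the 4-layer network the flatten dimension is $32 \times 5 \times 2 =
320$ and the parameter count is 55,618; `flatten_dim()` exposes the shape
calculus and is tested against an independent stepwise trace at all depths.
ReLU after the second hidden affine layer is an assumption (the hidden-layer
activation pattern is not forced by anything); no batch normalization or
dropout is used. The forward/backward pass and Adam live in C++
(RcppArmadillo) with an im2col formulation; gradients are verified against
central finite differences in the test suite.

Weights are initialized from the uniform fan-in scheme
$U(\pm 1/\sqrt{\text{fan-in}})$ under a dedicated seed; initialization,
batch shuffling, fold assignment, and augmentation each draw from distinct
derived streams so that every run is exactly reproducible and the streams do
not interact.

## Training and evaluation protocols

Training minimizes softmax cross-entropy with Adam (defaults: learning rate
$10^{-3}$, batch 64, ≤ 100 epochs, early-stopping patience 10 — all
unconstrained choices, exposed in `train_config()`). Evaluation is always at
*subject* level: segment PD-probabilities are averaged per subject and
thresholded at 0.5, ties counting as PD. Subject-level aggregation is the
only granularity at which a 20 + 20 independent test set can produce rates
like 3/20, and the mean-probability rule is the simplest aggregator
consistent with that; per-segment argmax voting is the obvious alternative
and was not taken because it discards calibration information.

Four protocols are provided:

* **train-100 %** — train on the whole cohort for the full epoch budget (no
  validation signal exists, so there is nothing to early-stop on) and
  evaluate once on the independent cohort.
* **holdout 70/30** — stratified subject-level split; the
  best-validation-epoch model is evaluated on the independent cohort.
* **five-fold CV, best-model / mean-model selection** — subject-independent
  stratified folds; each fold model is selected at its best validation
  epoch; the *best* rule picks the fold with the highest subject-level
  validation accuracy, the *mean* rule the fold closest to the across-fold
  mean, ties to the lowest fold index. "Validation performance" means
  subject-level accuracy throughout. The pooled validation decisions over
  all folds give a cross-validated accuracy; per-fold metrics are summarized
  as mean ± sample (n−1) SD.

Folds are stratified by class only. Every strategy asserts, on every run,
that train/validation/test subject sets are pairwise disjoint and that
augmented items derive only from training subjects.

## The synthetic cohort generator

Each recording is a syllable-pulse train: an 8-harmonic complex
(f0 ≈ 120 ± 15 Hz per subject, 1/h amplitudes, random phases) multiplied by
an amplitude envelope of per-syllable pulses (10 ms linear attack, 60 ms
exponential decay, τ = 25 ms), preceded by a 10 ms noise burst per syllable,
plus stationary Gaussian background noise. The envelope floor is
$1 - \text{mod depth}$, so modulation depth has its usual AM meaning.
Class structure enters through three deficit parameters applied to the PD
class: a syllable-rate reduction, a modulation-depth reduction, and a
background-noise excess; Gaussian between-subject random effects (SD 0.35
syllables/s on rate, 0.15 × that on depth) are truncated to valid ranges.
Defaults — HC 5.5 syllables/s, deficits 1.2 syllables/s, 0.35 depth,
0.02 noise amplitude — were fixed once from published DDK ranges (healthy
/pa-ta-ka/ rates of roughly 5–7 syllables/s, PD slower and more irregular)
and are intentionally *large* effects: the defaults define the separable
condition the calibration tests rely on.

Per-syllable timing jitter is Gaussian; its SD is 8 ms plus 10 ms per
syllable/s of configured rate deficit for the PD class. Tying the jitter
excess to the rate deficit (rather than to the class label) keeps the
all-deficits-zero cohort *exactly* class-symmetric, which the null
calibration requires.

One RNG substream per subject is derived by counter from the master seed
(HC and PD counters live in disjoint ranges), so enlarging a cohort never
reshuffles existing subjects, and identical spec + seed reproduces a cohort
bit-for-bit.

What the generator does **not** emulate: formant structure, phonetic
identity of /pa/ vs /ta/ vs /ka/, voice-quality perturbations (jitter /
shimmer in the phonatory sense), pauses, channel and room variability, or
any correlation with clinical scales. Passing tests on this generator
demonstrate that the pipeline's machinery is correct and calibrated, not
that the classifier would reach any particular accuracy on clinical speech.

## Numerical and degenerate-input choices

* All-zero signals cannot be peak-normalized and raise an error; an all-zero
  segment produces a uniform −80 dB matrix.
* Recordings shorter than one window yield zero segments plus a warning.
* Resampled lengths are forced to `round(n·16000/sr)` (trim or zero-pad by
  at most one sample) to keep the length contract exact across resampler
  versions.
* Result tables round half-up to two decimals (0.575 → 0.58), with a 1e-8
  guard absorbing binary representation error at tie boundaries; the
  across-fold SD uses the sample (n−1) convention.
* Pooling uses floor division; an architecture whose spatial size would
  reach zero is rejected at configuration time.

## Problem sizes used by the tests

The suite exercises the statistical properties at reduced, fixed scales
chosen once: calibration runs use 20 + 20 subjects with one 2 s recording
each and ≤ 30 epochs (null-effect CV accuracy must fall inside the 95 %
binomial chance band [0.35, 0.65] for 40 subjects; default-effect CV
accuracy must reach 0.9). The augmentation-does-not-hurt property uses a
deliberately hard cohort (12 + 12 subjects, 1.5 s, half-size effects) and
compares mean CV accuracy over five seeds between Cutting-Masking and
baseline; at 24 subjects the accuracy granularity (1/24) exceeds the 0.02
tolerance, so the comparison is made on the across-seed mean rather than
per seed. The analysis scripts under `analysis/` run the full-size
experiment (50 + 50 training subjects, 20 + 20 independent test).

## Known limitations

* The generator's class effects are caricatures; effect sizes, not just
  realism, drive the calibration outcomes.
* Training is single-threaded and sample-at-a-time; the network is small
  enough that this is fast, but the implementation does not scale to large
  architectures.
* No probability calibration, ROC analysis, or significance testing across
  methods is provided.
* The best/mean fold-selection rules select among fold *models*; they do not
  retrain on the full data after selection.
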