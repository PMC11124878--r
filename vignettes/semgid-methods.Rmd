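---
title: "Methods: sEMG biometric identification with semgid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG biometric identification with semgid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semgid)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of muscle
through skin electrodes. Because the interference pattern of many motor
units depends on a person's anatomy and electrode-to-muscle geometry, the
signal carries an individual signature that can be used as a behavioral
biometric: a clinic can identify a returning patient, or gate access to an
electronic health record, from a short recording of a hand gesture rather
than from a password alone.

`semgid` implements that pipeline end to end for two-channel recordings
organized as *subject x gesture (1-12) x session (1-3) x repetition
(1-10)*, sampled at 2000 Hz with 16-bit quantization. Each repetition is
one rest-contraction-rest execution of a gesture, with the contraction
lasting at least one second; sessions are separated by a day or more, so
the model has to tolerate day-to-day signal variability.

## The data model and plain-text layout

A `semg_record` holds a 2 x N sample matrix, the sampling rate, the four
labels, and 0-based half-open `[start, end)` bounds of the contraction
span. Datasets are written as one raw two-column TSV per repetition plus a
single header-bearing manifest (`file`, `start_index`, `end_index`,
`subject_id`, `gesture_id`, `session_id`, `repetition`). All metadata lives
in the manifest; signal files stay raw. One file per repetition was chosen
over index ranges into a pooled file because it keeps every unit of the
experimental design independently addressable; the reference database's
own layout does not disambiguate this, and no fidelity to it is claimed.
Amplitudes are stored as decimal text; the 16-bit ADC is available as an
optional quantization step in the generator rather than being forced on
file I/O, so round-trips are exact to text precision (1e-6 relative in the
tests).

## The synthetic generator

Access to the multi-session reference database requires a memorandum of
understanding, so the package ships a generator that reproduces the
*statistical structure* the pipeline relies on, not the physiology:

* **Carrier**: band-limited Gaussian noise, the standard surrogate for the
  sEMG interference pattern. Per channel, a subject's band is
  `peak_freq +/- bandwidth` with the peak drawn from 60-430 Hz and
  half-bandwidths of 15-30 Hz. The shaping is done in the frequency
  domain with a Gaussian magnitude profile (sd = bandwidth/2, so ~95% of
  the power lies inside the band) rather than with an IIR bandpass,
  because an IIR response peaks at the geometric band center — the
  frequency-domain profile keeps the empirical spectral mode exactly at
  the profile's peak frequency, which is the property the separability
  checks rely on.
* **Subject identity** is the two channels' spectral signature. Peaks are
  drawn with a guaranteed minimum pairwise separation (`delta`, default
  10 Hz), which makes identities learnable by construction — that is the
  point: downstream learnability tests are meaningful only if the planted
  signal exists.
* **Gesture identity** is the envelope shape: a raised-cosine trapezoid
  whose plateau emphasis (duty factor) varies with gesture id, with a slow
  sinusoidal modulation added for the "dynamic" gestures 7-12. Keeping
  gesture information out of the spectrum keeps subject identification the
  easier task, matching the pipeline's focus.
* **Session variability** is a multiplicative per-session gain drawn in
  [0.85, 1.15] — the smallest model that makes multi-session splits
  non-trivial. Per-window z-scoring largely removes it, which is exactly
  what a normalization stage should do.
* **Contamination**: optional 60 Hz mains and sub-5 Hz baseline-wander
  sinusoids, off by default, used to exercise the conditioning chain.
* **Timing**: 0.5 s rest, >= 1 s contraction, 0.5 s rest at 2000 Hz
  (4000 samples per repetition), with contraction gains of 4-8x the rest
  RMS of about 0.02 units.

Determinism: profiles are drawn from the dataset seed; each repetition
then draws from its own substream seeded by a hash of
`(seed, subject, gesture, session, repetition)`, so a record's samples do
not depend on generation order.

What the generator does **not** emulate: motor-unit action potentials and
recruitment, electrode placement and impedance drift, movement artifacts,
fatigue, or cross-talk between muscles. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that it
recovers planted structure; they say nothing about accuracy on real
recordings.

### Quality-control rules

The acquisition guideline "a signal whose magnitude is 20% higher than the
others is removed" is realized as: burst peak amplitude (over both
channels) strictly greater than 1.2x the leave-one-out median of the
group. The median is used because the guideline's "the others" must be
robust to the outlier itself; the strict inequality makes the 1.2x
boundary kept, which is the conservative reading. The envelope guideline is
realized as Pearson correlation of each record's 100 ms moving-average
rectified envelope against the leave-one-out group mean, with rejection
below 0.8. Both statistics are design choices — the guideline names no
formula — and both are exposed as parameters.

## Signal conditioning

The chain is a 60 Hz notch cascaded with an order-3 Butterworth bandpass
keeping 5-500 Hz, applied zero-phase (forward-backward) per channel.
Choices worth recording:

* **Cascade vs combined design**: the conditioning description admits
  either one filter with a notch or two cascaded filters; cascading is
  chosen because each stage is independently verifiable and the notch Q
  (30, i.e. a 2 Hz -3 dB width) can be tuned without re-deriving the
  bandpass.
* **Notch realization**: a standard RBJ biquad, hand-built because the
  available DSP library designs no notch.
* **Zero-phase application** avoids phase distortion at the cost of
  doubling the effective order; the documented magnitude response is the
  squared single-pass response (`filter_response(squared = TRUE)`).
* **Edge handling**: odd-reflection padding of 3x the filter length (21
  samples for the order-3 bandpass). Three filter lengths is the
  conventional padding for forward-backward filtering; padding by only
  three times the *order* leaves visible edge transients at the 5 Hz band
  edge.
* **Windowing**: model inputs are contraction-span windows (default 1 s),
  z-scored per channel per window. "Dimensionality reduction" is realized
  as windowing plus an optional integer decimation factor (default off;
  the scaled study uses 2, which keeps the whole 5-500 Hz band below the
  decimated Nyquist of 500 Hz).

## The residual network

The classifier is a 1D residual network: `n_blocks` stacked residual
blocks, each containing two sub-blocks of batch normalization, ReLU,
dropout and a 1D convolution (pre-activation order), with a MaxPool in the
first sub-block of every pooling block; the head is global average
pooling, a linear layer and softmax. The block output adds a shortcut copy
of the input — identity when shapes match, max-pooled when only the length
changed, max-pooled plus 1x1 convolution when the channel count changed.
(The pool-only shortcut for equal channel counts is a deliberate
simplification: a projection there would add parameters without changing
shapes.)

The canonical depth is 12 blocks. With pooling in *every* block a
2000-sample window shrinks 2^12-fold, which is infeasible; `build_model`
honors the canonical cadence as the default and fails fast with the
maximum feasible depth (10 for 2000 samples), while the documented
`pool_every = 2` switch makes the 12-block/2000-sample combination
runnable. Width (32 base filters doubling every 4 blocks), kernels (7
first, 5 after), dropout 0.3, He-uniform initialization, batch-norm
epsilon 1e-5 and momentum 0.9 are standard ResNet-1D practice, exposed in
`resnet_config`.

No deep-learning framework is used: forward and backward passes are
written directly in R as BLAS matrix products (convolution as a sum over
kernel taps of shifted-slab multiplications), trained with Adam on
categorical cross-entropy. The backward pass is verified against central
finite differences in the test suite, which is the strongest correctness
check available for hand-written gradients.

## Training, splitting and evaluation

Records are split 60:20:20 (train/validation/test) with the *repetition*
as the unit, stratified within each subject-by-gesture cell by
largest-remainder apportionment; all windows of a repetition land in one
partition, so no within-repetition leakage is possible. Training uses
Adam (learning rate 1e-3, batch 32), early stopping on validation loss
with patience 10, and restores the best-validation-loss weights.
Evaluation reports per-class precision, recall and F1, overall accuracy,
macro and support-weighted averages, and the confusion matrix; argmax ties
break to the lowest class index, and repetition-level predictions are
majority votes over a repetition's windows with ties broken by the highest
mean probability. Zero-denominator classes get metric 0 with a warning.
Support-weighted recall equals accuracy identically for single-label
multiclass data, which the suite asserts as an algebraic invariant.

## Verification and access modes

Enrollment stores a subject's template: the mean of per-record mean-window
embeddings (the global-average-pool activations). Verification compares a
probe's mean-window embedding to the claimed template by cosine
similarity — chosen because it is scale-invariant, which matters when
sessions differ by a gain. Thresholds are calibrated at the equal-error
point: sweep every observed score, take the candidate minimizing
|FAR - FRR| (ties toward the lower threshold), and report the mean of FAR
and FRR there. *General* access requires the salted-SHA-256 credential
check and then the biometric check, and reports which factor failed;
*emergency* access uses the biometric factor alone. A softmax-identity
score would be a workable alternative decision variable; templates over
embeddings were chosen because they extend to subjects enrolled after
training without retraining the head.

## Scaled study sizes

The package's worked example, tests and acceptance script run a scaled
study chosen to exercise every stage on ordinary hardware: 5 subjects with
10 Hz peak separation, gestures 1-3 (450 repetitions; the full 12-gesture
design is generated where only counts are checked), decimation 2, 1 s
windows (1000 decimated samples), a 4-block/16-filter network with
`pool_every = 2` (9673 parameters), and 15 training epochs. On this
configuration the repetition-level test accuracy is at or near 1.0 and
training takes a couple of minutes on one CPU core. These sizes are the
package's reference configuration, not a claim about the full-scale
problem: the published full-database accuracies are expressly out of reach
without the restricted data, and nothing here should be read as
reproducing them.

## Known limitations

* The generator's subject signature (separated spectral peaks) is far
  cleaner than real inter-subject differences; real-data accuracy will be
  lower and electrode repositioning between sessions is not modeled at
  all.
* Batch normalization uses per-batch statistics with running-average
  inference; very small batches give noisy estimates, so batch sizes below
  ~8 are not recommended with this implementation.
* The pure-R network is practical at the scaled sizes above (seconds per
  epoch), but the full 12-block configuration on long windows is slow to
  *train* in R; it builds and runs forward passes fine, and the
  architecture code is the contract, not a performance claim.
* QC rules operate within one (subject, gesture, session) group and assume
  >= 2 records; the original guideline's re-acquisition step is modeled as
  reject-and-regenerate, which a generator can always do.
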