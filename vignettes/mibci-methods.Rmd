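---
title: "Decoding motor imagery for closed-loop glove control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery for closed-loop glove control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The problem

Motor imagery (MI) — mentally rehearsing a movement without executing it —
modulates the sensorimotor rhythms of the EEG: the mu (alpha-band, ~8–13 Hz)
and beta (~13–30 Hz) oscillations over motor cortex desynchronize, i.e. lose
power, during imagined movement. A brain–computer interface can decode this
event-related desynchronization (ERD) from scalp EEG and use it to drive an
assistive device. `mibci` implements such a stack end to end for a pneumatic
soft rehabilitation glove: a subject imagines closing a fist; a classifier
detects the MI state from 1-second EEG windows; a discrete-time controller
translates the decoded intent into pump and valve commands that inflate or
deflate the glove, under hard pressure-safety limits.

Because neither human recordings nor glove hardware are available to an
offline package, both ends are simulated: a synthetic-EEG generator stands in
for the subjects and a first-order pneumatic plant for the hardware. Both are
first-class, tested components, not fixtures.

## The acquisition protocol being emulated

The generator reproduces a three-phase block protocol: motor execution,
motor imagery, and rest, each phase lasting 16 s, six trials per session,
three sessions per subject — 864 s of annotated task data in total. Phase
order is randomized within trials (seed-deterministically). Downstream, the
first and last 3 s of every phase are cropped to remove transitional
activity, and the remaining 10 s per phase are cut into 1-second windows
with 0.75 s overlap (0.25 s hop), giving `floor((10 - 1)/0.25) + 1 = 37`
epochs per phase and 666 per class per subject. Motor-execution epochs are
excluded from classifier training by default; the decoded classes are
`fist` (motor imagery) and `rest`.

## The synthetic EEG model

Each channel is a sum of three components:

* pink noise (1/f power spectrum) at `noise_scale` µV RMS (default 10 µV),
  the canonical EEG background;
* a band-limited alpha oscillator (Gaussian spectral profile centred at
  10 Hz, width 1 Hz) at `alpha_amp` (default 8 µV RMS);
* a band-limited beta oscillator (20 Hz, width 2 Hz) at `beta_amp`
  (default 4 µV RMS).

The discriminative structure is injected by per-phase amplitude envelopes:
during movement phases (executed or imagined) the alpha and beta oscillators
on the sensorimotor channels (`C3`, `C4`, `F3`, `F4` by default) are scaled
by `1 - effect_size` — the ERD. During rest, alpha on all channels may be
scaled by `rest_alpha_gain`. The default is `rest_alpha_gain = 1`, so that
`effect_size = 0` produces MI and rest segments from literally the same
distribution; this makes the null construction exact and is verified by a
two-sample test in the suite. `effect_size` is the single dial a user should
think of as "subject quality": 0 is an uninformative subject, 0.8 a very
clean one.

What the generator deliberately does **not** model: ocular and muscle
artifacts, electrode drift and popping, inter-channel volume-conduction
correlation, non-stationarity across sessions. A green end-to-end test
therefore establishes that the pipeline recovers a known spectral contrast
at realistic amplitudes and SNR — not that it would survive every artifact
of a real recording.

All generation is bit-reproducible: identical (profile, protocol, seed)
inputs give identical sample arrays.

## Preprocessing

The filter chain is a 4th-order Butterworth bandpass (0.5–45 Hz) followed by
a biquad notch (60 Hz, Q = 30), both applied forward–backward (zero phase)
so epoch timing is unaffected. No IIR design code was available in the
target environment, so the designs are implemented from first principles
(analog prototype → lowpass-to-bandpass transform → bilinear transform,
second-order sections; RBJ biquad for the notch) with the filter recursion
in C++. The magnitude response was cross-validated against an independent
reference implementation to 1e-12 during development, and the suite asserts
the behavioural contract: ≥ 99% rejection at 60 Hz, ≤ 5% loss at 10 Hz,
DC annihilated.

Cropping is annotation-level: the continuous signal is kept intact (so the
filters never see artificial segment edges) and only the epoch-eligible
intervals shrink. The train/test split assigns whole trials to one side:
with 75% overlap, neighbouring windows share most of their samples, and any
within-trial split would leak test data into training. This is also why the
epoch-batch generator fabricates pseudo-trial provenance: the leakage-safe
splitter is the only splitter the package offers.

## Featurization

Each 1-second, 16-channel epoch is transformed by FFT into a `44 x 16`
matrix: magnitude at integer frequencies 1–44 Hz (half-open `[1, 45)`;
1-second windows make the bin spacing exactly 1 Hz) for each channel.
Features are z-scored per channel across the 44 bins before entering the
model; raw magnitudes are kept for band-power analysis. Band powers use the
canonical delta/theta/alpha/beta/gamma partition with half-open bands
(shared edges belong to the upper band), so the five band powers sum to the
total spectral power; at 1 Hz resolution the delta band is effectively
`[1, 4)`. No taper is applied before the FFT by default — the windows are
short and the features are consumed by a learned model, so spectral leakage
is part of the (consistent) representation rather than a bias to correct.

## The classifier

The decoder is a small transformer encoder operating on the 44 frequency
bins as sequence positions, with the 16 channels as the embedding:

* sinusoidal positional encoding added to the input (non-learned; the
  reference parameter table shows its addition costing 0 parameters);
* encoder block 1: 4-head self-attention (head size 64), dropout, residual
  add, layer norm, then a feed-forward expansion 16 → 128 → 16 (ReLU),
  residual add, layer norm;
* encoder block 2: attention sub-layer only — the reference layer graph
  shows the second block without its feed-forward sub-layer, and the
  default follows that graph literally; `symmetric_blocks = TRUE` restores
  a conventional second block;
* global average pooling over the 44 positions, then a dense head
  128 → 64 → 2 with batch norm, dropout and layer norm between layers, and
  a softmax output (class 0 = rest, class 1 = fist).

With the default configuration the per-layer parameter counts reproduce the
reference architecture exactly (attention 17,168; FFN 2,176/2,064; head
2,176/8,256/130; layer norms 32/32/256/128; batch norms 512/256), which the
acceptance suite pins cell by cell.

Training minimizes focal loss, `FL = -alpha_c (1 - p_c)^gamma log p_c`, with
`gamma = 2` and `alpha` proportional to inverse class frequency (normalized
to mean 1). Focal loss down-weights confidently-classified examples; with
`gamma = 0` and unit weights it reduces to cross-entropy, which the tests
assert. The optimizer is Adam (learning rate 1e-3, batch size 32) with
validation-loss early stopping (patience 10) and best-weight restoration.
Forward and backward passes are hand-implemented in base R matrix code
(attention, layer/batch norm, dropout, pooling and the focal-loss gradient),
and verified against finite differences in the test suite. Training is
single-threaded and bit-deterministic given the seed.

Choices the source material left open, decided here: ReLU as the FFN and
head nonlinearity; dropout 0.1 in the encoder and 0.3 in the head; the
attention parameterization with per-head 16 → 64 query/key/value projections
plus biases and a 256 → 16 output projection (the unique common convention
reproducing the published attention parameter count); sinusoidal rather
than learned positional encoding.

## Evaluation

Accuracy, F1, Cohen's Kappa and AUC, with the 2×2 confusion matrix and the
ROC curve. F1 is reported for the `fist` class — the minority, actionable
class. Kappa uses the marginal chance term from the confusion matrix. AUC
is the trapezoidal area under the threshold ROC, which equals pairwise
counting with half credit for ties; the suite verifies each metric against
an independent brute-force implementation on hundreds of random cases at
1e-9. Pooling across subjects is the arithmetic mean of each scalar metric.

## The controller

The control loop runs at the decoder's epoch hop (0.25 s per step; the
source gives no loop rate, so the decoder stream sets it). Each step:
decode intent from the current spectral feature, branch, then safety-check.
With fist intent and pressure inside `[P_min, P_max)` the pressurizing pump
runs (target `P_t + ΔP`); at or above `P_max` the vacuum pump runs —
bang-bang regulation around the ceiling. Rest intent holds (pumps off,
passive leak) by default; a `vent` rest behaviour is available, matching
the alternative prose description of the rest branch. The safety layer then
vents and *stops* the system if pressure strictly exceeds `P_max` (an
absorbing state until an explicit reset, which re-derives `P_min` from the
current reading), and opens the vent to stabilize if pressure falls below
`P_min`.

One boundary decision: the reference branch guard is strict at both ends
(`P_min < P_t < P_max`), but `P_min` is *defined* as the initial sensor
reading — with a noise-free plant the very first step would deadlock at
`P_t = P_min` forever. The lower bound is therefore inclusive here. The
redundancy between the `s_t = 1, P_t ≥ P_max` vacuum branch and the
layered safety vent is preserved as written, not resolved.

The plant is first-order: each commanded pump step changes pressure by
`gain`, a leak pulls toward ambient, an open vent relaxes exponentially,
and the sensor adds Gaussian noise. `ΔP = 5`, `P_max = 50`, `gain = 2` (kPa)
are simulator conventions — the source prints no pressure numbers or units —
and live in configuration, not code.

## Numerical and degenerate-input conventions

* Layer-norm epsilon 1e-5, batch-norm epsilon 1e-3, momentum 0.9.
* `p_c` is clipped at 1e-12 inside the focal loss.
* Decision ties (`P(fist)` exactly at threshold) resolve to fist.
* Zero-variance feature channels z-score to zeros rather than NaN.
* Intervals shorter than one window yield zero epochs, silently; phases too
  short to crop raise an error naming the trial.
* Grouped splits keep at least one group on each side regardless of
  rounding, and fail loudly if a partition ends up single-class.
* EDF export quantizes to 16 bits over each channel's observed physical
  range and pads the final record to a whole second.

## Known limitations

* The generator's channel-level ERD placement is a modelling convention,
  not a claim about where real subjects express the contrast.
* Per-subject results from the original experiments are not reproducible
  here: the raw recordings were never deposited, and the train/test split
  was unreported. The package's acceptance checks are therefore structural
  (architecture, counts, closed forms, oracles) and behavioural
  (recovery of known synthetic contrasts, controller safety), not numeric
  replications of per-subject tables.
* Training at realistic data sizes (hundreds of epochs) takes tens of
  seconds in pure R; the implementation favours verifiability over speed.
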