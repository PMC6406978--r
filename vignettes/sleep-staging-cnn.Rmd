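---
title: "Automated sleep staging with a 19-layer 1D-CNN: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated sleep staging with a 19-layer 1D-CNN: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcnn)
```

## The problem

Overnight polysomnography (PSG) is scored by experts into sleep stages on
consecutive 30-second epochs. Under the Rechtschaffen–Kales taxonomy the
stages are wake (W), four NREM stages S1–S4, and REM; the AASM revision
merges S3 and S4 into slow-wave sleep (SWS). Manual scoring is slow and
subjective, which motivates end-to-end classifiers that map a raw signal
epoch directly to a stage, with no hand-crafted features.

`sleepcnn` implements such a classifier: a fixed 19-layer one-dimensional
convolutional network that consumes a scaled 30-s epoch (3000 samples at
100 Hz) of single-channel EEG (Fpz–Cz), single-channel horizontal EOG, or
both stacked as two channels, and emits a softmax distribution over 2–6
sleep classes. The same architecture is used unchanged for every class
count and signal choice; only the width of the softmax layer follows the
class count.

## The architecture

`build_model_spec(nb_class, input_channels)` constructs the network
declaratively and derives, per layer, the output shape under valid
(unpadded) convolution/pooling,

$$L_\text{out} = \left\lfloor \frac{L_\text{in} - k}{s} \right\rfloor + 1,$$

and the trainable parameter counts $f(kc+1)$ for a convolution with $f$
filters, kernel $k$, and $c$ input channels, and $n_\text{in}u + u$ for a
dense layer with $u$ units.

```{r}
build_model_spec(3, 1)
```

Two cells of the published layer table are internally inconsistent and
were reconciled from the redundant columns: the second convolution is
printed with kernel 5, but both its parameter count (24,704) and its
output length (997 from 999 at stride 1) independently imply kernel 3;
the eighth is printed as "256 × 7", but its parameter count (262,272),
its printed output (128 × 233 from length 240), and the ninth layer's
parameter count (which requires 128 input channels) all imply 128 filters
of kernel 8. Two corroborating columns outrank one, so the derived table
uses kernel 3 and 128 × 8 respectively; every other printed shape and
count is reproduced exactly, which is what the acceptance tests pin down.

The dual-signal configuration enters as a two-channel input of length
3000 rather than a concatenated 6000-sample vector: only the stacked
reading preserves the printed 3000-sample input and the first-layer
output length of 999. The first convolution then has
$64(5\cdot2+1) = 704$ parameters instead of the single-channel 384; all
downstream shapes are unchanged.

Choices the reference description leaves open, fixed here:

* **Loss**: categorical cross-entropy, the canonical pairing with a
  softmax output.
* **Initialisation**: Glorot-uniform, seeded (`init_weights()`).
* **Dropout** (rate 0.2, after the first pooling block and after the
  penultimate dense activation) is inverted dropout, identity at
  inference.
* **Decay**: the published "decay = 0.003" is read as the classical
  per-update inverse-time learning-rate decay
  $\eta_t = \eta_0 / (1 + 0.003\,t)$ — the convention of the framework
  generation the model was built with. $t$ counts weight updates.
* **Model selection**: final-epoch weights; no early stopping.

## Training and evaluation

`sleep_cnn()` trains with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$), defaults learning rate $10^{-4}$, decay 0.003,
100 epochs, batch 128 (batch size is unstated in the reference protocol;
128 is the package default and configurable). All stochastic elements —
initialisation, batch shuffling, dropout — derive from one integer seed,
so a fit is bit-reproducible on a fixed single-threaded BLAS.

`split_dataset(n, seed)` reproduces the 70/15/15 split law: validation
and test take $\lceil 0.15n \rceil$ samples each and training the
remainder, giving the published 10,630/2,279/2,279 at $n = 15{,}188$ and
89,258/19,127/19,127 at $n = 127{,}512$. The split is one seeded uniform
shuffle, not stratified — the reference protocol fixes only the seed.

`evaluate()` builds the confusion matrix by argmax (rows true, columns
predicted) and reports accuracy (trace over total) plus per-class
precision, sensitivity and F1; a class never predicted or never present
scores 0 with a warning rather than NaN.

Numerical precision is a template parameter of the compiled engine.
Training defaults to single precision — the standard arithmetic of deep
learning frameworks, and about twice the throughput of double on a
BLAS-backed CPU — while `precision = "double"` runs the identical code
path in double, which the test suite uses to compare the convolution
against a direct sliding-inner-product oracle at $10^{-6}$.

## Preprocessing

Epochs are scaled per epoch and per channel: standardize (mean 0, sample
standard deviation 1, $n-1$ divisor as in `sd()`), then min–max to
$[0,1]$. The reference pipeline states only "standardization and
normalization to the zero-to-one range"; the order is forced
(standardization alone cannot land in $[0,1]$), and per-epoch scope keeps
epochs i.i.d. and matches a segment-level pipeline — whether the original
authors scaled per epoch or per recording is not stated, so this is a
package decision, not an inference about their code. Degenerate constant
epochs map to all zeros after standardization and all 0.5 after min–max,
with a warning. No filtering or artifact rejection is applied anywhere,
deliberately.

Stage bookkeeping: tokens `M` (movement time) and anything unrecognised
(`?`, `X`, ...) are mapped to `MOVEMENT`/`UNSCORED` and eliminated by
`filter_ambiguous()` before modelling. `class_distribution()` truncates
percentages to two decimals rather than rounding, because that is the
convention the reference composition table actually follows (604/15,188
prints as 3.97, not 3.98).

One oddity is left as found: the sleep-edf documentation describes
Pz–Oz as an EEG derivation while the reference dataset description calls
it a chin EMG; the reader treats channel labels verbatim and loads
exactly what is requested, so the discrepancy never needs resolving.

## The synthetic PSG generator

Real sleep-EDF recordings cannot ship with a package, so
`generate_dataset()` simulates stage-labelled PSG that is learnable by
the same pipeline:

* **Hypnogram**: a sticky Markov chain over the six stages,
  $P = p\,I + (1-p)\,\mathbf{1}\pi^\top$ with persistence $p = 0.4$ and
  stationary law $\pi = (0.22, 0.18, 0.20, 0.09, 0.09, 0.22)$ over
  (W, S1, S2, S3, S4, REM). This family has $\pi$ as its exact
  stationary distribution, so stage frequencies are known in closed
  form; the default $\pi$ makes the five-class problem (S3+S4 merged)
  roughly balanced, with no class above ~22%.
  `imbalanced_transition()` instead draws i.i.d. stages at the
  wake-dominated proportions of the sleep-edf composition table, for
  exercising class-imbalance behaviour.
* **Signals**: per stage and channel, a sum of narrow-band sinusoids
  (frequency jittered and phase randomised each epoch), Hann-windowed
  transient bursts arriving as a Poisson process, and white noise.
  Defaults follow textbook signatures: dominant alpha (8–12 Hz) EEG and
  blink transients in wake; theta slowing in S1; 13 Hz spindle bursts in
  S2; high-amplitude delta in S3 and especially S4; low-amplitude
  mixed-frequency EEG with large slow EOG deflections in REM. Amplitudes
  are in microvolts and quantisation through the 16-bit EDF writer is
  part of the round trip the tests check.

These signatures are fixture parameters chosen for learnable spectral
separation, not physiological claims: there is no K-complex morphology,
no EMG tone, no artifacts, no inter-subject variability, and class
boundaries are far cleaner than in real PSG. Tests passing on this
generator therefore demonstrate that the pipeline and optimiser work,
not that real-data accuracies are reproduced — reproducing those
requires the public databases and the full 100-epoch protocol (see the
README).

## Problem sizes used by the test suite

The architecture, splitting, metric and convolution checks are instant.
The end-to-end learnability check uses 2,000 synthetic epochs,
five classes, single-channel EEG, and a 10-epoch training run at batch
32 with learning rate $10^{-3}$ — the rate is scaled up tenfold because
the schedule is ten times shorter than the reference 100-epoch protocol,
whose $10^{-4}$ remains the package default. Held-out accuracy is
required to reach at least 0.60 against a 0.20 chance level. A
label-shuffling control is trained for 3 epochs (enough updates to
overfit noise if leakage existed) and must stay within [0.14, 0.26] —
i.e. at chance — on the held-out set.

## Known limitations

* No patient-level (subject-wise) splitting: epochs are split i.i.d.,
  so the evaluation is signal-level, as in the reference protocol.
* The EDF reader covers standard 16-bit EDF/EDF+ with per-record
  annotation streams; it does not handle discontinuous (EDF+D) files or
  logarithmic transducer scaling.
* Class imbalance is handled only by exposure (the generator option and
  the per-class metrics); there is no loss re-weighting.
* Training is CPU-only and single-threaded; a full sleep-edfx run
  (127k epochs, 100 epochs of training) is out of desk-scale reach and
  documented as a recipe rather than a test.
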