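---
title: "Cross-subject emotion decoding from sparse-channel EEG: model, adaptation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject emotion decoding from sparse-channel EEG: model, adaptation, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeglwf)
```

## The problem

Wearable brain-computer interfaces favor very few electrodes. This package
decodes self-rated valence and arousal (1-9 scales, thresholded at 5 into
low/high classes or four quadrants) from four prefrontal channels (FP1, FP2,
F3, F4). Two obstacles dominate: the little spatial information four
electrodes carry, and inter-subject variability — a decoder trained on a
pool of subjects often transfers poorly to a new one. The package implements
a three-phase answer: (1) pre-train a multi-scale spatio-temporal CNN on the
pooled source subjects, (2) adapt it to a new subject using only a small
labeled fraction of that subject's data (2% by default) with Learning
without Forgetting (LwF), and (3) predict the remainder.

## The network

Each input is one 1 s window, a `c x f` matrix in `[0,1]` (4 channels by
128 or 100 samples). Four stages follow.

**Temporal stage.** Three parallel valid convolutions with kernels
`(1, floor(m^i * f))`, `i = 1,2,3`, `m = 0.5` — widths 64/32/16 at
`f = 128` — each with 128 filters, leaky rectification (slope 0.01) and
average pooling of width 8. The three pooled maps are concatenated along
the *time* axis (the only axis on which valid-convolution branches of
different widths are conformable) and batch-normalized. At `f = 128` the
concatenated time length is `⌊65/8⌋ + ⌊97/8⌋ + ⌊113/8⌋ = 8 + 12 + 14 = 34`.

**Spatial stage.** A global kernel `(c, 1)` and a local kernel
`(floor(m·c), 1) = (2, 1)` (15 filters each, leaky rectification, average
pool 2) concatenated along the *space* axis: the global branch contributes
one row and the local branch `c - 1` rows, so 4 rows at `c = 4`. Published
tables for this architecture print a 3-row output here, which is not
conformable with any valid concatenation of these two branches; the
package documents and tests its own (1 + (c-1))-row convention instead.

**Fusion stage.** Four separable-convolution blocks (depthwise then
pointwise 1x1, batch norm, rectification, max pool). Block 1 is 2-D with a
`(3, 1)` depthwise kernel along space and a `(1, 4)` max pool along time;
its output is flattened into a single 1-D sequence; blocks 2-4 are 1-D
with kernel 3, channels 32/64/128, max pool 2. The resulting lengths at
`f = 128` are 120 → 59 → 28 → 13, giving a 128 x 13 map (1664 features).
These shapes come from the package's closed-form shape functions, which
tests compare against executed forward traces over a grid of geometries.

**Classifier head.** Three fully connected layers (hidden sizes 64 and 16
— the layer count is prescribed, the widths are this package's choice)
with batch norm, rectification and dropout 0.5 between them, then a
softmax.

Convolutions are all valid (no padding) with floor-mode pooling — the only
combination that reproduces the published temporal length 34. Activations
in the two convolutional stages are leaky; the fusion and head use plain
rectification. Initialization is fan-in-scaled uniform under a fixed seed.

The engine behind these stages is written in the package: convolutions are
lowered to BLAS matrix products via im2col, every layer has an analytic
backward pass (verified in tests against central finite differences at
every stage), and the optimizer is Adam (`lr = 1e-3`, batch 128 by
default). The memory-bound elementwise and pooling kernels are small
compiled (Rcpp) routines.

## Adaptation with Learning without Forgetting

The pre-trained network (parameters `theta_s` for the feature stages,
`theta_o` for the head) becomes a frozen *teacher*. The *student* inherits
`theta_s` bit-for-bit and re-initializes its head `theta_n'`. A fraction
(default 2%, `ceiling`-rounded: 48 of 2400, 17 of 840) of the new
subject's windows is drawn uniformly with a fixed seed as the incremental
set; the rest is test data. For 15 epochs the student minimizes

  `L = L_new + lambda * L_old`,

where `L_new` is the cross-entropy against the true incremental labels and
`L_old` is the cross-entropy between *temperature-rescaled* teacher and
student rows: each probability is raised to `1/T` and renormalized
(`T = 2`, `lambda = 0.1`). Rescaling probabilities (not logits) follows
the original LwF formulation; the uniform row is a fixed point and `T = 1`
is the identity. The gradient of the distillation term through the student
logits is `(s - q) / (T N)` with `s`, `q` the rescaled student and teacher
rows — the implementation uses this closed form rather than numeric
differentiation. With `lambda = 0` the loop reduces exactly — same RNG
stream, bit-identical trajectory — to plain fine-tuning, which is also the
"without LwF" ablation arm.

All student parameter groups remain trainable during adaptation; the
teacher participates only through its (eval-mode) soft targets and is
bit-identical before and after, which tests assert.

## Batch-normalization statistics at desk scale

Batch norm uses batch statistics while training and stored statistics at
prediction. The conventional exponential update (momentum 0.1 from an
initial variance of 1) is fine after thousands of steps, but the package's
test-scale runs take tens of steps, after which the stored statistics are
still dominated by their initialization and eval-mode outputs collapse.
After each training phase the package therefore recalibrates: one pass
over that phase's training data (the source set after pre-training, the
incremental set after adaptation) replaces the stored moments with
cumulative batch averages, dropout disabled, parameters untouched. After
long training both schemes coincide; at short horizons recalibration is
what makes eval-mode behavior reflect the trained model. Re-estimating the
student's statistics from the incremental windows also nudges
normalization toward the target subject's distribution, which is part of
how adaptation helps.

## The synthetic generator

Real sparse-channel corpora in this field are gated or unreleased, so the
package ships a generator whose class structure is known by construction.
Each channel of a trial is a sum of band-limited sinusoids at theta /
alpha / beta / gamma centers (6, 10, 20, 35 Hz — all inside the 4-45 Hz
analysis band), with random phases, a 1/f background shaped onto 1-45 Hz,
and white noise (defaults: sd 0.2 and 0.25 against unit-order band
amplitudes). Valence is encoded as frontal alpha asymmetry: the
alpha-amplitude difference between F4 and F3 (half-weight on FP2/FP1) is
`tanh((valence - 5)/2) * 0.6`, scaled by a per-subject asymmetry gain;
arousal scales beta+gamma amplitude by `tanh((arousal - 5)/2) * 0.5`.
Both effects vanish exactly at the rating midpoint 5 and during the
trial's leading baseline segment. Ratings are drawn balanced over the low
and high halves of each scale and, by default, avoid the ambiguous
`(4.5, 5.5)` band around the class threshold; a flag restores uniform
`[1, 9]` sampling.

Inter-subject shift is controlled by one scalar. Per subject it scales:
channel-gain deviations from 1 (sd 0.2), band-center jitter (sd 1 Hz), and
asymmetry-gain deviations from 1 (sd 0.75, *unclamped*). The last is the
deliberate centerpiece: at shift 1-1.5 some subjects express the valence
effect weakly or with inverted sign, which is the realistic reason
cross-subject valence transfer fails, and it reproduces the regime the
method targets — un-adapted transfer near chance for some targets, large
gains from a few labeled windows. With small shifts the synthetic task is
trivially transferable (per-window min-max normalization already removes
gain differences) and the adaptation machinery has nothing to show.

Everything is a pure function of the seed: subject draws come from
`(seed, subject_id)`, trial phases and noise from `(seed, subject_id,
trial_id)`, so any subject's slice can be regenerated independently.

What the generator does *not* emulate: volume conduction, ocular/muscle
artifacts, non-stationarity within trials, 1/f slope variation, or any
label noise in the ratings. Passing tests on this generator demonstrate
that the pipeline, network, losses and protocol behave as specified —
not that the accuracy levels transfer to real recordings.

## Preprocessing

Stage order: polyphase resampling to the profile rate (downsampling only),
baseline removal (keep the tail), 4th-order Butterworth 4-45 Hz band-pass
applied forward-backward (zero phase; the order is prescribed, zero-phase
filtering is standard EEG practice), channel selection to FP1/FP2/F3/F4,
non-overlapping 1 s windows (floor count, trailing samples dropped), and
per-channel min-max normalization to `[0, 1]` *within each window* — the
strictest reading of per-channel normalization after segmentation, and the
one that removes inter-window amplitude leakage; a constant channel maps
to all zeros. Ratings at exactly 5 are "high" everywhere, matching the
quadrant definitions' `>= 5`; the binary wording leaves 5 unassigned, and
one rule is used throughout. The DEAP-like profile is 40 x 63 s (3 s
baseline) at 128 Hz → 2400 windows/subject; the EPPVR-like profile is
14 x 70 s (10 s baseline) at 100 Hz → 840.

## Evaluation protocol

Leave-one-subject-out: each subject in turn is the target; the others are
pooled for pre-training; adaptation uses the target's incremental split
and testing its remainder; everything repeats (5 times by default) with
per-repeat seeds `base + repeat - 1`, re-drawing both the split and the
head initialization (the published protocol fixes one seed yet reports a
nonzero spread over 5 repeats, so per-repeat offsets are necessary; both
the split and the initialization are re-drawn because neither is singled
out). Metrics: accuracy, F-score (`TP/(TP + (FP+FN)/2)` with "high" as
positive; macro-averaged one-vs-rest for the 4-class task, the
conservative convention), and confusion matrices with rows as actual
classes. Significance uses a two-tailed paired t-test over per-subject
accuracies (the test family is unnamed in the source material; paired t
matches the reported statistic's form). Summaries report mean and
standard deviation pooled over subjects and repeats, with per-subject
tables alongside. The incremental-size sweep re-runs only the adapt+test
arm over fractions 0.5-5%, sharing one pre-trained teacher per
(subject, repeat), and compares each fraction to the smallest by paired t.

## Problem sizes used by the tests

The structural count checks run the full 32- and 30-subject geometries,
streamed one subject at a time. The stochastic experiments use 100 Hz
windows (`f = 100`): the generator's gamma band (35 Hz) and the 45 Hz
band-pass edge require sampling above ~96 Hz, so the smaller published
geometry is the natural desk scale. The adaptation experiment freezes 6
subjects x 8 trials of 13 s, shift 1.5, a 25% incremental fraction and 12
replicates rotating the target subject; pre-training uses 3 epochs at
batch 64. The null-calibration check uses 3 subjects with the class
effect switched off and asserts pooled leave-one-subject-out accuracy
within three standard errors of chance. These sizes are the package's
choices for routine verification; the defaults of every function remain
the full published values (100/15 epochs, batch 128, 2% split, seed 42).

## Known limitations

The retention advantage of the distillation term over plain fine-tuning,
while in the expected direction and maximized near `lambda = 0.1` in a
sweep, is small at desk scale (about +0.01 accuracy on the source domain)
and inherently noisy across head re-initializations. Headline accuracies
from gated real datasets are not reproduced here by design; the package's
claims are structural and behavioral. The CNN engine is single-threaded
apart from BLAS and sized for desk-scale experiments, not GPU-scale
training.
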