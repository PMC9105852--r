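---
title: "Tone-curve correction and its effect on ROI classification: methods"
author: "ToneROI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tone-curve correction and its effect on ROI classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToneROI)
```

## The problem

B-mode liver ultrasound shows cirrhotic parenchyma as slightly lighter,
coarser texture than healthy tissue, but the difference is subtle and buried
in speckle. A practical question for computer-aided diagnosis pipelines that
classify small regions of interest (ROIs) is whether a cheap, global
grey-level correction — a tone curve applied identically to every pixel —
can improve the image quality enough to lower the classification error of a
downstream learner. ToneROI implements a family of eight such corrections as
lookup tables, a shallow convolutional network and classical baselines to
classify 32×32 single-channel ROIs, and the statistical harness needed to
measure whether a correction helps: repeated stratified holdout with
Student-t confidence intervals, parameter sweeps under shared splits,
cross-validated parameter selection, and paired method comparison.

## The tone-curve family

With `f` the input grey level, `g` the output, and `fmax` the maximum
representable level (255 for 8-bit, 4095 for 12-bit):

| type | formula | parameter | effect |
|------|---------|-----------|--------|
| 0 | `g = f` | — | identity (no correction) |
| I | `g = 0` if `f < t`, else `f` | `t ∈ [0, fmax]` | black out dark pixels |
| II | `g = 0` if `f < t`, else `fmax(f−t)/(fmax−t)` | `t ∈ [0, fmax−1]` | black out + stretch contrast |
| III | `g = fmax (f/fmax)^(1/γ)` | `γ > 0` | gamma curve (γ<1 darkens) |
| IV | `g = fmax − f` | — | inversion |
| V | `g = fmax − f` if `f < t`, else `0` | `t ∈ [0, fmax]` | inversion, light pixels ignored |
| VI | `g = fmax(1 − f/t)` if `f < t`, else `0` | `t ∈ [1, fmax]` | steepened inversion |
| VII | `g = fmax ((fmax−f)/fmax)^(1/γ)` | `γ > 0` | inverse gamma curve |

Types I–III enhance contrast among originally light pixels; IV–VII do the
same for originally dark pixels after inversion. The family satisfies exact
algebraic relations that the test suite verifies entry-by-entry: type 0,
I(t=0), II(t=0) and III(γ=1) are the identity; IV is an involution;
V(t=fmax) and VII(γ=1) equal IV.

### Numerical choices

The formulas produce reals; pixels are integers. Outputs are **rounded half
away from zero** and clipped to `[0, fmax]`. Round-half-away was chosen over
R's default round-half-to-even so that golden values are independent of the
parity of the integer part and stable across platforms; on the non-negative
grey domain it is simply `floor(g + 0.5)`.

Threshold comparisons are strict (`f < t`), so a pixel exactly at the
threshold always takes the "otherwise" branch. The two degenerate parameter
values that would divide by zero — II with `t = fmax` and VI with `t = 0` —
are rejected at construction rather than patched with a limiting value: the
standard parameter grids never touch them, and a silent limit would hide a
configuration error. For the gamma types at `f = 0` (and VII at `f = fmax`)
the power `0^(1/γ)` is defined as 0 for every `γ > 0`, the continuity limit.

Curves are compiled once into a lookup table of `fmax + 1` entries
(`buildLUT()`), and `applyCurve()` is a single table lookup per pixel; the
test suite proves the table equals direct formula evaluation at every input
level, every grid parameter, and both bit depths.

## The synthetic ROI generator

The clinical datasets such corrections target are rarely shareable, so the
package carries a generator that emulates the relevant population structure:
two classes of 32×32 8-bit speckle patches, 200 normal and 300 cirrhosis by
default, with cirrhosis slightly lighter (`muNormal = 90`,
`muCirrhosis = 110`).

Each ROI is `clip(round(mu * S))` where `S` is a unit-mean multiplicative
speckle field: i.i.d. Rayleigh draws scaled to mean 1, smoothed with a
Gaussian kernel (`correlationSigma = 1` pixel by default) to give speckle
its grain, and with the deviation from unit mean amplified by
`speckleScale`. A raw Rayleigh field has a fixed coefficient of variation
(≈ 0.52) and smoothing only lowers it, so the amplification step is what
makes noise a tunable: `speckleScale → 0` is the noiseless limit, and the
default `speckleScale = 2` restores a per-pixel coefficient of variation of
roughly 0.3 after smoothing. The defaults were chosen once so that the
default task is hard but learnable — the CNN's holdout error sits well away
from both 0% and the 40% majority-class floor — and they are fixture
parameters, not claims about ultrasound physics.

What the generator does **not** emulate: log-compression and scan-conversion
artefacts, depth-dependent attenuation, anatomical structure (vessels,
ligaments), inter-patient variability, and any genuine texture difference
between classes beyond the mean shift (a `correlationSigma` pair can add a
grain-size difference, but it is off by default). Passing tests on synthetic
data therefore demonstrate that the machinery is correct and that the
pipeline can detect a planted class difference — not that any tone curve
helps on clinical images.

## The shallow CNN

Small medical datasets overfit deep networks, so the classifier is
deliberately shallow: two blocks of 3×3 convolution (32 filters, same-size
padding, ReLU) each followed by 2×2 max-pooling, taking 32×32 input to
16×16 then 8×8; the 32×8×8 = 2048-dimensional flattening feeds a
2048–100–2 fully connected head with ReLU, dropout 0.5 between the hidden
and output layers, and softmax output. Same-size padding is forced by the
32→32→16 shape sequence; dropout sits after the hidden dense layer.
Training minimizes cross-entropy with ADAM (learning rate 0.001, moments
0.9/0.999), batch size 400 — i.e. full batch for the canonical 400-image
training set — for 100 epochs.

The implementation (in compiled code, `src/cnn.cpp`) draws weight
initialization (He-scaled normals), epoch shuffling and dropout masks from
one seeded Mersenne Twister stream, so training is bit-reproducible for a
given seed. Inputs are scaled to `[0, 1]` by division by `fmax` — a
deliberate, documented choice: per-image standardization would partially
undo the tone curves whose effect is the object of study, whereas a fixed
global division preserves it.

The harness's stochastic end-to-end checks use a reduced schedule of 3
trials × 30 epochs with batch size 100. Batch 100 (4 parameter updates per
epoch) rather than the canonical 400 is the package's choice for short
schedules: 30 full-batch epochs would give ADAM only 30 update steps, too
few for any optimizer to be informative, while 120 updates suffice for the
wide-margin synthetic tasks these checks use. Problem sizes used by the
test suite and the acceptance script (500-image datasets, 2–3 trials,
10–30 epochs) were fixed alongside this schedule.

## The evaluation harness

**Repeated stratified holdout.** Each trial samples, per class and without
replacement, 160 of 200 normal and 240 of 300 cirrhosis images for
training; the 40 + 60 remaining form the test set, so each trial partitions
the data. The error rate is the percentage of misclassified test images.
Ten trials are summarized by the mean error and the 95% Student-t half-width
`qt(0.975, 9) · sd / √10`. The t-interval on so few trials assumes
approximate normality of per-trial errors; with all trials equal the width
is exactly 0, and a single trial reports `NA` rather than a fake width.

**Paired design.** `makeSplits()` derives per-trial split seeds *and*
per-trial classifier seeds from one base seed, and every method evaluated
against a given `HoldoutSplits` object sees byte-identical splits and
training streams. Summaries record a hash of the split indices;
`compareMethods()` refuses to pair summaries whose hashes differ (an
unpaired Welch test is available behind a flag). This pairing is what makes
the sweep identity exact: a sweep row at the identity parameter (I/II with
`t = 0`, III with `γ = 1`) reproduces the uncorrected run trial-by-trial,
bit for bit — a property the acceptance tests assert with the CNN itself.

**Comparison test.** Differences between methods are tested with a paired
two-sided t-test on per-trial error differences. Degenerate inputs are
handled explicitly rather than delegated: identical error vectors give
`p = 1`; constant nonzero differences have zero variance and a divergent
statistic, reported as `p = 0` with an infinite statistic as a documented
sentinel.

**Parameter selection.** `selectParameter()` implements the recommended
procedure for choosing `t` or `γ` in practice: stratified 3- or 5-fold
cross-validation of each candidate under shared folds, selecting the
candidate with the smallest average error. Ties break toward the smaller
parameter value — the milder correction — which is deterministic and favours
staying close to the identity.

## Design choices that were genuinely open

* **Rounding rule** — no rounding convention is inherent to the transfer
  functions; round-half-away is this package's commitment (above).
* **Splits shared across methods** — whether comparisons should reuse splits
  is open in principle; the package forces sharing, because paired designs
  have strictly more power for the same budget and make identity checks
  exact. Consequently its p-values are paired-t p-values, and no claim is
  made of reproducing any externally reported unpaired value.
* **ADAM's learning rate and moments, dropout placement, weight
  initialization** — standard defaults, fixed and recorded, chosen before
  any evaluation; the architecture constants (32 filters, 100 hidden units,
  dropout 0.5) are part of the method family itself.
* **LDA on 1024 pixel features** — with 400 training images the pooled
  covariance is singular; the standard fit is attempted first and a
  ridge-regularized pooled-covariance discriminant (diagonal loading of
  `1e-3 · mean(diag)`) is the documented fallback.
* **Baseline hyperparameters** — linear SVM at `C = 1`, Euclidean k-NN,
  100-tree random forest; features are the flattened `[0, 1]`-scaled pixels
  themselves, matching the CNN's input contract so comparisons are
  like-for-like.

## Known limitations

* The generator's realism is deliberately minimal (see above); conclusions
  about clinical benefit require clinical data.
* The CNN is CPU-bound and single-threaded; the canonical 10-trial,
  100-epoch protocol on 500 images takes tens of minutes, which is why the
  stochastic acceptance checks use the reduced schedule.
* Bit-reproducibility of CNN training holds for a fixed platform and
  compiler; across platforms, floating-point reordering may change
  last-bit results (the split machinery, by contrast, is exactly
  reproducible everywhere).
* 12-bit data travels in two-byte PGM containers; the bundled PNG writer is
  8-bit only.

## A worked example

```{r example, eval = FALSE}
library(ToneROI)

ds <- generateDataset(syntheticConfig(seed = 7))
sp <- makeSplits(ds, splitSpec(baseSeed = 7))
cnn <- cnnClassifier(cnnConfig(seed = 7), epochs = 30L, batchSize = 100L)

uncorrected <- runHoldout(ds, toneCurve(0), cnn, sp)
corrected <- runHoldout(ds, toneCurve("VI", t = 200), cnn, sp)
compareMethods(corrected, uncorrected)
```
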