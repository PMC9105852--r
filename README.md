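# ToneROI

Grey-level tone-curve correction for small B-mode ultrasound regions of
interest (ROIs), and the statistical machinery to measure whether a
correction improves downstream classification of liver tissue as normal or
cirrhotic.

Cirrhotic parenchyma appears slightly lighter than healthy tissue in B-mode
imaging, but the difference is subtle and buried in speckle. A cheap global
grey-level transform — a tone curve, applied identically to every pixel via
a lookup table — can re-shape the intensity distribution before a classifier
sees the image. ToneROI provides:

* **Eight tone-curve operators** mapping input level `f ∈ [0, fmax]` to
  output `g` (`fmax` = 255 for 8-bit, 4095 for 12-bit):
  * type 0: `g = f` (identity)
  * type I: `g = 0` if `f < t`, else `f`
  * type II: `g = 0` if `f < t`, else `fmax (f − t)/(fmax − t)`
  * type III: `g = fmax (f/fmax)^(1/γ)` (gamma curve)
  * type IV: `g = fmax − f` (inversion)
  * type V: `g = fmax − f` if `f < t`, else `0`
  * type VI: `g = fmax (1 − f/t)` if `f < t`, else `0`
  * type VII: `g = fmax ((fmax − f)/fmax)^(1/γ)`

  Outputs are computed in real arithmetic, rounded half away from zero and
  clipped; curves compile to lookup tables (`buildLUT()`) applied per pixel
  (`applyCurve()`).
* **A synthetic speckle ROI generator** (`generateDataset()`) emulating a
  two-class population of 32×32 8-bit patches — 200 normal + 300 cirrhosis
  by default, cirrhosis slightly lighter — as a unit-mean smoothed Rayleigh
  speckle field multiplying the class mean.
* **A shallow CNN** (`trainCNN()`): 2 × [3×3 conv (32 filters) + ReLU + 2×2
  max-pool] → flatten 2048 → dense 100 + ReLU → dropout 0.5 → softmax over
  {normal, cirrhosis}, trained with ADAM; implemented in compiled code with
  fully seeded randomness.
* **Classical baselines** on flattened pixel vectors: k-NN (k = 1, 3, 5),
  linear SVM, LDA, random forest (100 trees).
* **The evaluation harness**: repeated stratified holdout (10 trials of
  160 + 240 train / 40 + 60 test by default), mean error with 95% Student-t
  half-width `qt(0.975, n−1)·sd/√n`, parameter sweeps under shared splits,
  3/5-fold cross-validated parameter selection (`selectParameter()`), and
  paired t-test comparison that refuses to pair results from different
  splits (`compareMethods()`).

## Worked example

Does type VI correction with `t = 200` change a 3-NN classifier's holdout
error on a synthetic dataset?

```r
library(ToneROI)

curve <- toneCurve("VI", t = 200)
ds <- generateDataset(syntheticConfig(seed = 7))   # 200 normal + 300 cirrhosis
sp <- makeSplits(ds, splitSpec(baseSeed = 7))      # 10 shared stratified splits
knn <- baselineSpec("kNN", k = 3)

uncorrected <- runHoldout(ds, toneCurve(0), knn, sp)
corrected   <- runHoldout(ds, curve, knn, sp)
uncorrected
#> EvalSummary [0+3-NN]: mean error 16.90% ± 1.45 (95% CI, 10 trials)
corrected
#> EvalSummary [VI(t=200)+3-NN]: mean error 16.20% ± 1.42 (95% CI, 10 trials)

compareMethods(corrected, uncorrected)
#> $meanDiff
#> [1] -0.7
#> $statistic
#> [1] -2.688774
#> $df
#> [1] 9
#> $pValue
#> [1] 0.02484634
#> $paired
#> [1] TRUE
```

Reading: averaged over ten shared train/test splits, correction VI(t = 200)
lowers this baseline's error from 16.90% to 16.20%; because both methods saw
byte-identical splits, the paired t-test attributes the −0.7 percentage-point
mean difference a p-value of 0.025. (Numbers are for the synthetic fixture
above; they say nothing about clinical data.) Swap `knn` for
`cnnClassifier(cnnConfig(seed = 7))` to run the CNN instead, and use
`sweepCurve()` / `selectParameter()` to explore `t` and `γ` grids.

A thin command-line front end over the same functions ships in
`inst/scripts/toneroi.R` with subcommands `simulate`, `correct`,
`train-eval`, `sweep`, `select` and `baselines`.

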