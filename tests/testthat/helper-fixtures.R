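# Shared fixture builders. Everything is generated in code; no files.

# A dataset of constant-intensity images: `values` per class label.
constantDataset <- function(nNormal, nCirrhosis, valueNormal, valueCirrhosis,
                            side = 32L, fmax = 255L) {
  n <- nNormal + nCirrhosis
  arr <- array(0L, c(side, side, n))
  vals <- rep(c(valueNormal, valueCirrhosis), c(nNormal, nCirrhosis))
  for (i in seq_len(n)) arr[, , i] <- vals[i]
  labeledDataset(arr, rep(c("normal", "cirrhosis"), c(nNormal, nCirrhosis)),
                 fmax = fmax)
}

# A small speckle dataset with the canonical 2:3 class ratio, scaled down.
smallSpeckleDataset <- function(nNormal = 20L, nCirrhosis = 30L, side = 8L,
                                gap = 20, seed = 42L) {
  generateDataset(syntheticConfig(
    nNormal = nNormal, nCirrhosis = nCirrhosis, size = side,
    muNormal = 100 - gap / 2, muCirrhosis = 100 + gap / 2, seed = seed))
}

# Split spec matching a scaled-down 2:3 dataset (per-class 80/20 holdout).
smallSplitSpec <- function(nTrials = 5L, nNormal = 20L, nCirrhosis = 30L,
                           baseSeed = 7L) {
  splitSpec(nTrials = nTrials,
            trainNormal = as.integer(0.8 * nNormal),
            trainCirrhosis = as.integer(0.8 * nCirrhosis),
            testNormal = nNormal - as.integer(0.8 * nNormal),
            testCirrhosis = nCirrhosis - as.integer(0.8 * nCirrhosis),
            baseSeed = baseSeed)
}

# Independent real-arithmetic oracle for the eight transfer functions,
# written from the printed formulas; deliberately separate from the package
# implementation path (no ToneCurve objects, no LUTs).
oracleToneCurve <- function(type, f, t = NA, gamma = NA, fmax = 255) {
  g <- switch(as.character(type),
    "0" = f,
    "1" = ifelse(f < t, 0, f),
    "2" = ifelse(f < t, 0, fmax * (f - t) / (fmax - t)),
    "3" = fmax * (f / fmax)^(1 / gamma),
    "4" = fmax - f,
    "5" = ifelse(f < t, fmax - f, 0),
    "6" = ifelse(f < t, fmax * (1 - f / t), 0),
    "7" = fmax * ((fmax - f) / fmax)^(1 / gamma))
  pmin(pmax(sign(g) * floor(abs(g) + 0.5), 0), fmax)
}
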