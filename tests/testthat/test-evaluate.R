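test_that("stratified splits hit the exact per-class counts and partition the data", {
  ds <- generateDataset(syntheticConfig(size = 8, seed = 1))
  sp <- makeSplits(ds, splitSpec(baseSeed = 3))
  expect_length(sp@trials, 10L)
  labs <- roiLabels(ds)
  for (tr in sp@trials) {
    expect_length(tr$train, 400L)
    expect_length(tr$test, 100L)
    expect_equal(sum(labs[tr$train] == "normal"), 160L)
    expect_equal(sum(labs[tr$train] == "cirrhosis"), 240L)
    expect_equal(sum(labs[tr$test] == "normal"), 40L)
    expect_equal(sum(labs[tr$test] == "cirrhosis"), 60L)
    expect_length(intersect(tr$train, tr$test), 0L)
    expect_identical(sort(c(tr$train, tr$test)), seq_len(500L))
  }
})

test_that("splits are deterministic in the base seed and vary across seeds", {
  ds <- generateDataset(syntheticConfig(size = 8, seed = 1))
  a <- makeSplits(ds, splitSpec(baseSeed = 5))
  b <- makeSplits(ds, splitSpec(baseSeed = 5))
  expect_identical(a@trials, b@trials)
  expect_identical(splitHash(a), splitHash(b))
  expect_identical(a@classifierSeeds, b@classifierSeeds)
  c <- makeSplits(ds, splitSpec(baseSeed = 6))
  expect_false(identical(a@trials, c@trials))
  expect_false(identical(splitHash(a), splitHash(c)))
})

test_that("a count mismatch is reported with expected vs found", {
  ds <- generateDataset(syntheticConfig(nNormal = 199, size = 8, seed = 1))
  expect_error(makeSplits(ds, splitSpec()), "expected 200.*found 199")
})

test_that("a constant-prediction stub scores the majority-class error with zero width", {
  ds <- generateDataset(syntheticConfig(size = 8, seed = 2))
  sp <- makeSplits(ds, splitSpec(baseSeed = 4))
  s <- runHoldout(ds, toneCurve(0), constantClassifier("cirrhosis"), sp)
  expect_equal(meanError(s), 40)
  expect_equal(ciHalfwidth(s), 0)
  expect_identical(perTrialErrors(s), rep(40, 10))
  oracle <- runHoldout(ds, toneCurve(0), oracleClassifier(), sp)
  expect_equal(meanError(oracle), 0)
})

test_that("per-trial misclassified and correct test images always sum to the test size", {
  ds <- smallSpeckleDataset(20, 30, gap = 10, seed = 3)
  sp <- makeSplits(ds, smallSplitSpec())
  s <- runHoldout(ds, toneCurve(2, t = 20), baselineSpec("kNN", k = 3), sp)
  expect_equal(s@nTest, 10L)
  # error rates are multiples of 100 / nTest
  expect_true(all(abs(perTrialErrors(s) %% 10) < 1e-9))
})

test_that("the Student-t interval matches the stats::t.test oracle", {
  planted <- c(30, 30, 30, 30, 30, 40, 40, 40, 40, 40)
  hw <- tCIHalfwidth(planted)
  ci <- stats::t.test(planted)$conf.int
  expect_equal(hw, diff(ci) / 2, tolerance = 1e-12)
  expect_equal(hw, 3.7699, tolerance = 1e-4)   # 2.2622 * 5.2705 / sqrt(10)
  expect_equal(tCIHalfwidth(rep(35, 10)), 0)
  expect_true(is.na(tCIHalfwidth(35)))
  set.seed(1)
  for (i in 1:10) {
    x <- runif(sample(3:12, 1), 0, 100)
    expect_equal(tCIHalfwidth(x), diff(stats::t.test(x)$conf.int) / 2,
                 tolerance = 1e-12)
  }
})

test_that("the CI half-width shrinks as roughly 1/sqrt(n) for replicated trials", {
  # closed form for k copies of x (n = 4): sum of squared deviations scales
  # with k, so hw_k = qt(.975, 4k-1) * sqrt(S k / (4k-1)) / sqrt(4k)
  x <- c(30, 35, 40, 45)
  S <- sum((x - mean(x))^2)
  hw <- function(k) qt(0.975, 4 * k - 1) * sqrt(S * k / (4 * k - 1)) / sqrt(4 * k)
  expect_equal(tCIHalfwidth(rep(x, 4)), hw(4), tolerance = 1e-12)
  expect_equal(tCIHalfwidth(rep(x, 16)), hw(16), tolerance = 1e-12)
  # asymptotically the ratio approaches sqrt(1/4)
  expect_equal(tCIHalfwidth(rep(x, 400)) / tCIHalfwidth(rep(x, 100)), 0.5,
               tolerance = 0.01)
})

test_that("paired comparison matches the t.test oracle and enforces shared splits", {
  mk <- function(err, hash = "abc") ToneROI:::.evalSummary("m", err, hash, 100L)
  a <- mk(c(31, 35, 28, 40, 33, 36, 30, 29, 38, 34))
  b <- mk(c(33, 36, 30, 39, 36, 38, 31, 33, 40, 33))
  cmp <- compareMethods(a, b)
  ht <- stats::t.test(perTrialErrors(a), perTrialErrors(b), paired = TRUE)
  expect_equal(cmp$pValue, ht$p.value, tolerance = 1e-9)
  expect_equal(cmp$statistic, unname(ht$statistic), tolerance = 1e-9)
  expect_equal(cmp$meanDiff, mean(perTrialErrors(a) - perTrialErrors(b)))
  expect_equal(cmp$df, 9)
  # identical errors -> p = 1, difference 0
  same <- compareMethods(a, a)
  expect_equal(same$pValue, 1)
  expect_equal(same$meanDiff, 0)
  # constant nonzero differences -> documented p = 0 sentinel
  shifted <- mk(perTrialErrors(a) + 2)
  degen <- compareMethods(shifted, a)
  expect_equal(degen$pValue, 0)
  expect_equal(degen$statistic, Inf)
  # split hash mismatch refuses pairing but allows Welch
  other <- mk(perTrialErrors(b), hash = "zzz")
  expect_error(compareMethods(a, other), "split hashes differ")
  welch <- compareMethods(a, other, paired = FALSE)
  expect_equal(welch$pValue,
               stats::t.test(perTrialErrors(a), perTrialErrors(b))$p.value,
               tolerance = 1e-12)
})

test_that("sweeps share one set of splits and cover the documented grids", {
  ds <- smallSpeckleDataset(20, 30, gap = 40, seed = 6)
  sp <- makeSplits(ds, smallSplitSpec(nTrials = 3))
  cls <- meanThresholdClassifier(100)
  res1 <- sweepCurve(ds, 1, seq(20, 160, by = 20), cls, sp)
  expect_length(res1, 8L)
  expect_named(res1, sprintf("I(t=%d)", seq(20, 160, by = 20)))
  res3 <- sweepCurve(ds, 3, c(1/10, 1/5, 1/3, 1/2, 1, 2, 3, 5), cls, sp)
  expect_length(res3, 8L)
  expect_true(all(vapply(res3, splitHash, character(1)) == splitHash(sp)))
  # identity parameter reproduces the type-0 run trial-by-trial
  t0 <- runHoldout(ds, toneCurve(0), cls, sp)
  expect_identical(perTrialErrors(res3[["III(gamma=1)"]]), perTrialErrors(t0))
  res1b <- sweepCurve(ds, 1, c(0, 40), cls, sp)
  expect_identical(perTrialErrors(res1b[["I(t=0)"]]), perTrialErrors(t0))
  tab <- summaryTable(res1, parameters = seq(20, 160, by = 20))
  expect_equal(names(tab), c("method", "parameter", "meanError", "ciHalfwidth"))
  expect_equal(nrow(tab), 8L)
})

test_that("identity-family curves leave holdout results unchanged", {
  ds <- smallSpeckleDataset(10, 15, gap = 30, seed = 12)
  sp <- makeSplits(ds, smallSplitSpec(nTrials = 2, nNormal = 10, nCirrhosis = 15))
  cls <- meanThresholdClassifier(100)
  base <- runHoldout(ds, toneCurve(0), cls, sp)
  for (cv in list(toneCurve(1, t = 0), toneCurve(2, t = 0),
                  toneCurve(3, gamma = 1))) {
    expect_identical(perTrialErrors(runHoldout(ds, cv, cls, sp)),
                     perTrialErrors(base), info = curveLabel(cv))
  }
})

test_that("cross-validated selection returns the planted argmin with the tie rule", {
  # Constant-intensity classes: normal = 100, cirrhosis = 140. Under type I
  # with threshold t, values below t become 0, so the stub's decisions -- and
  # hence the CV error -- are an exactly computable function of t.
  # class counts divisible by 3 and 5 keep every fold at the same 1:2 ratio,
  # so the planted error is exact for both fold counts
  ds <- constantDataset(15, 30, 100L, 140L, side = 8L)
  cls <- meanThresholdClassifier(50)
  candidates <- c(0, 110, 150, 200)
  plantedError <- vapply(candidates, function(t) {
    vN <- if (100 < t) 0 else 100   # corrected normal value
    vC <- if (140 < t) 0 else 140   # corrected cirrhosis value
    predN <- ifelse(vN > 50, "cirrhosis", "normal")
    predC <- ifelse(vC > 50, "cirrhosis", "normal")
    100 * ((predN != "normal") / 3 + 2 * (predC != "cirrhosis") / 3)
  }, numeric(1))
  expect_equal(plantedError, c(100 / 3, 0, 200 / 3, 200 / 3))
  for (k in c(3L, 5L)) {
    sel <- selectParameter(candidates, ds, 1, cls, folds = k, seed = 2)
    expect_equal(sel$best, 110)
    expect_equal(sel$table$cvMeanError, plantedError, tolerance = 1e-9)
  }
  # tie between two zero-error candidates resolves to the smaller value
  cls2 <- meanThresholdClassifier(120)
  sel2 <- selectParameter(c(0, 110), ds, 1, cls2, folds = 3, seed = 2)
  expect_equal(sel2$best, 0)
  # single candidate; empty candidate list
  expect_equal(selectParameter(7, ds, 1, cls, folds = 3)$best, 7)
  expect_error(selectParameter(numeric(0), ds, 1, cls), "no candidate")
  expect_error(selectParameter(c(10, 20), ds, 1, cls, folds = 4), "folds")
})
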