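#' SplitSpec: the repeated stratified holdout protocol
#'
#' Defaults follow the canonical protocol: 10 trials, each splitting 200
#' normal + 300 cirrhosis images into 400 training (160 normal, 240
#' cirrhosis) and 100 test (40 normal, 60 cirrhosis) images by per-class
#' sampling without replacement.
#'
#' @slot nTrials number of random splits.
#' @slot trainNormal,trainCirrhosis,testNormal,testCirrhosis per-class
#'   counts; train + test must equal the dataset's class counts.
#' @slot baseSeed seed from which per-trial split seeds and per-trial
#'   classifier seeds are spawned, so adding methods never perturbs splits.
#'
#' @seealso [splitSpec()], [makeSplits()], [runHoldout()]
#' @export
setClass("SplitSpec",
         representation(nTrials = "integer", trainNormal = "integer",
                        trainCirrhosis = "integer", testNormal = "integer",
                        testCirrhosis = "integer", baseSeed = "integer"))

setValidity("SplitSpec", function(object) {
  counts <- c(object@nTrials, object@trainNormal, object@trainCirrhosis,
              object@testNormal, object@testCirrhosis)
  if (any(is.na(counts)) || any(counts < 1L)) {
    return("all trial and per-class counts must be positive integers")
  }
  TRUE
})

#' Configure the repeated holdout protocol
#'
#' @param nTrials number of random stratified splits (default 10).
#' @param trainNormal,trainCirrhosis per-class training counts (160, 240).
#' @param testNormal,testCirrhosis per-class test counts (40, 60).
#' @param baseSeed integer seed.
#' @return a [SplitSpec-class].
#' @export
splitSpec <- function(nTrials = 10L, trainNormal = 160L, trainCirrhosis = 240L,
                      testNormal = 40L, testCirrhosis = 60L, baseSeed = 1L) {
  new("SplitSpec", nTrials = as.integer(nTrials),
      trainNormal = as.integer(trainNormal),
      trainCirrhosis = as.integer(trainCirrhosis),
      testNormal = as.integer(testNormal),
      testCirrhosis = as.integer(testCirrhosis),
      baseSeed = as.integer(baseSeed))
}

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf(paste0("SplitSpec: %d trials, train %d normal + %d cirrhosis, ",
                     "test %d normal + %d cirrhosis, baseSeed=%d\n"),
              object@nTrials, object@trainNormal, object@trainCirrhosis,
              object@testNormal, object@testCirrhosis, object@baseSeed))
})

#' HoldoutSplits: materialized train/test index pairs
#'
#' Produced by [makeSplits()]; carries a hash of all indices (so paired
#' comparisons can verify two summaries saw identical splits) and one
#' classifier seed per trial (so every method evaluated on these splits also
#' shares per-trial training randomness).
#'
#' @slot trials list of `list(train=, test=)` integer index vectors.
#' @slot classifierSeeds integer vector, one per trial.
#' @slot hash character fingerprint of the splits.
#' @slot spec the generating [SplitSpec-class].
#' @export
setClass("HoldoutSplits",
         representation(trials = "list", classifierSeeds = "integer",
                        hash = "character", spec = "SplitSpec"))

#' @export
setMethod("length", "HoldoutSplits", function(x) length(x@trials))

#' @export
setMethod("splitHash", "HoldoutSplits", function(x) x@hash)

setMethod("show", "HoldoutSplits", function(object) {
  tr <- object@trials[[1]]
  cat(sprintf("HoldoutSplits: %d trials, %d train / %d test, hash %s\n",
              length(object@trials), length(tr$train), length(tr$test),
              object@hash))
})

#' Draw the repeated stratified holdout splits
#'
#' Per trial, training indices are sampled without replacement within each
#' class at exactly the specified counts; the remaining images form the test
#' set, so each trial partitions the dataset. Deterministic in
#' `spec@baseSeed`. The returned object is reused across every method being
#' compared (paired design).
#'
#' @param dataset a [LabeledDataset-class] whose class counts equal
#'   train + test per class.
#' @param spec a [SplitSpec-class].
#' @return a [HoldoutSplits-class].
#' @export
makeSplits <- function(dataset, spec = splitSpec()) {
  stopifnot(is(dataset, "LabeledDataset"), is(spec, "SplitSpec"))
  validObject(spec)
  counts <- classCounts(dataset)
  need <- c(normal = spec@trainNormal + spec@testNormal,
            cirrhosis = spec@trainCirrhosis + spec@testCirrhosis)
  for (cl in ROI_CLASSES) {
    if (counts[[cl]] != need[[cl]]) {
      .stopf("class '%s': expected %d images (train %d + test %d), found %d",
             cl, need[[cl]],
             if (cl == "normal") spec@trainNormal else spec@trainCirrhosis,
             if (cl == "normal") spec@testNormal else spec@testCirrhosis,
             counts[[cl]])
    }
  }
  seeds <- .spawnSeeds(spec@baseSeed, 2L * spec@nTrials)
  splitSeeds <- seeds[seq_len(spec@nTrials)]
  classifierSeeds <- seeds[spec@nTrials + seq_len(spec@nTrials)]
  idxNormal <- which(roiLabels(dataset) == "normal")
  idxCirr <- which(roiLabels(dataset) == "cirrhosis")
  trials <- vector("list", spec@nTrials)
  allIdx <- integer(0)
  for (i in seq_len(spec@nTrials)) {
    set.seed(splitSeeds[i])
    trN <- sort(sample(idxNormal, spec@trainNormal))
    trC <- sort(sample(idxCirr, spec@trainCirrhosis))
    train <- c(trN, trC)
    test <- sort(c(setdiff(idxNormal, trN), setdiff(idxCirr, trC)))
    trials[[i]] <- list(train = train, test = test)
    allIdx <- c(allIdx, train, 0L, test, 0L)
  }
  new("HoldoutSplits", trials = trials,
      classifierSeeds = as.integer(classifierSeeds),
      hash = .hashInts(allIdx), spec = spec)
}

#' EvalSummary: aggregated holdout error of one method
#'
#' Per-trial error rates (percent misclassified test images), their mean,
#' and the 95% Student-t confidence half-width
#' `qt(0.975, nTrials - 1) * sd / sqrt(nTrials)`.
#'
#' @slot method method identifier (curve label + classifier).
#' @slot perTrial numeric vector of per-trial error rates in percent.
#' @slot meanError arithmetic mean of `perTrial`.
#' @slot ciHalfwidth 95% CI half-width (0 iff all trials equal; `NA` for a
#'   single trial).
#' @slot splitHash fingerprint of the splits used.
#' @slot nTest test images per trial.
#' @aliases perTrialErrors meanError ciHalfwidth splitHash methodId
#' @seealso [runHoldout()], [compareMethods()]
#' @export
setClass("EvalSummary",
         representation(method = "character", perTrial = "numeric",
                        meanError = "numeric", ciHalfwidth = "numeric",
                        splitHash = "character", nTest = "integer"))

setValidity("EvalSummary", function(object) {
  if (any(object@perTrial < 0 | object@perTrial > 100)) {
    return("per-trial error rates must lie in [0, 100] percent")
  }
  if (abs(object@meanError - mean(object@perTrial)) > 1e-9) {
    return("meanError must equal the mean of the per-trial error rates")
  }
  TRUE
})

#' 95% Student-t confidence half-width
#'
#' `qt(0.975, n - 1) * sd(x) / sqrt(n)`; 0 when all values are equal,
#' `NA` for fewer than two values.
#'
#' @param x numeric vector of per-trial error rates.
#' @param level confidence level (default 0.95).
#' @return Numeric scalar.
#' @export
tCIHalfwidth <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
}

.evalSummary <- function(method, perTrial, hash, nTest) {
  new("EvalSummary", method = method, perTrial = as.numeric(perTrial),
      meanError = mean(perTrial),
      ciHalfwidth = if (length(perTrial) < 2L) NA_real_ else tCIHalfwidth(perTrial),
      splitHash = hash, nTest = as.integer(nTest))
}

#' @export
setMethod("perTrialErrors", "EvalSummary", function(x) x@perTrial)
#' @export
setMethod("meanError", "EvalSummary", function(x) x@meanError)
#' @export
setMethod("ciHalfwidth", "EvalSummary", function(x) x@ciHalfwidth)
#' @export
setMethod("splitHash", "EvalSummary", function(x) x@splitHash)
#' @export
setMethod("methodId", "EvalSummary", function(x) x@method)

setMethod("show", "EvalSummary", function(object) {
  cat(sprintf("EvalSummary [%s]: mean error %.2f%% ± %.2f (95%% CI, %d trials)\n",
              object@method, object@meanError, object@ciHalfwidth,
              length(object@perTrial)))
})

#' @export
setMethod("as.data.frame", "EvalSummary", function(x, ...) {
  data.frame(method = x@method, trial = seq_along(x@perTrial),
             errorRate = x@perTrial, meanError = x@meanError,
             ciHalfwidth = x@ciHalfwidth, splitHash = x@splitHash,
             stringsAsFactors = FALSE)
})

#' Estimate a method's error rate by repeated stratified holdout
#'
#' For each trial: the tone curve is applied to training and test images,
#' the classifier is fitted on the corrected training images with the
#' trial's classifier seed, and the error rate is the percentage of
#' misclassified corrected test images. The identity curve (type 0) means
#' "no correction".
#'
#' @param dataset a [LabeledDataset-class].
#' @param curve a [ToneCurve-class] (type 0 for no correction).
#' @param classifier a [ClassifierSpec-class].
#' @param splits a [HoldoutSplits-class], or a [SplitSpec-class] from which
#'   splits are drawn. Pass the same `HoldoutSplits` to every method being
#'   compared.
#' @return an [EvalSummary-class].
#' @examples
#' ds <- generateDataset(syntheticConfig(nNormal = 20, nCirrhosis = 30, seed = 1))
#' sp <- makeSplits(ds, splitSpec(nTrials = 3, trainNormal = 16,
#'                                trainCirrhosis = 24, testNormal = 4,
#'                                testCirrhosis = 6))
#' runHoldout(ds, toneCurve(0), constantClassifier("cirrhosis"), sp)
#' @export
runHoldout <- function(dataset, curve, classifier, splits = splitSpec()) {
  stopifnot(is(dataset, "LabeledDataset"), is(curve, "ToneCurve"),
            is(classifier, "ClassifierSpec"))
  if (is(splits, "SplitSpec")) splits <- makeSplits(dataset, splits)
  stopifnot(is(splits, "HoldoutSplits"))
  corrected <- applyCurve(dataset, curve)
  truth <- roiLabels(corrected)
  perTrial <- vapply(seq_along(splits@trials), function(i) {
    tr <- splits@trials[[i]]
    pred <- fitPredict(classifier, corrected[tr$train], corrected[tr$test],
                       seed = splits@classifierSeeds[i])
    100 * mean(pred != truth[tr$test])
  }, numeric(1))
  .evalSummary(sprintf("%s+%s", curveLabel(curve), classifierLabel(classifier)),
               perTrial, splits@hash, length(splits@trials[[1]]$test))
}

#' Sweep a tone-curve parameter grid under shared splits
#'
#' Runs [runHoldout()] once per parameter value with one shared set of
#' splits, so rows are directly comparable (paired design).
#'
#' @param dataset a [LabeledDataset-class].
#' @param curveType tone-curve type (1, 2, 5, 6 sweep `t`; 3, 7 sweep
#'   `gamma`).
#' @param grid numeric vector of parameter values.
#' @param classifier a [ClassifierSpec-class].
#' @param splits a [HoldoutSplits-class] or [SplitSpec-class].
#' @return List of [EvalSummary-class], one per grid value, in grid order;
#'   see [summaryTable()] for a tabular view.
#' @export
sweepCurve <- function(dataset, curveType, grid, classifier,
                       splits = splitSpec()) {
  if (length(grid) == 0L) .stopf("parameter grid is empty")
  type <- .parseCurveType(curveType)
  if (is(splits, "SplitSpec")) splits <- makeSplits(dataset, splits)
  curves <- lapply(grid, function(v) .curveWithParam(type, v, fmaxLevel(dataset)))
  res <- lapply(curves, function(cv) runHoldout(dataset, cv, classifier, splits))
  names(res) <- vapply(curves, curveLabel, character(1))
  res
}

# Build a curve of `type` with the swept parameter bound to the right slot.
.curveWithParam <- function(type, value, fmax) {
  if (type %in% .T_TYPES) return(toneCurve(type, t = value, fmax = fmax))
  if (type %in% .GAMMA_TYPES) return(toneCurve(type, gamma = value, fmax = fmax))
  toneCurve(type, fmax = fmax)
}

#' Tabulate sweep results
#'
#' @param summaries list of [EvalSummary-class] (e.g. from [sweepCurve()]).
#' @param parameters optional numeric vector of the swept parameter values.
#' @return data.frame with columns `method`, `parameter` (if given),
#'   `meanError`, `ciHalfwidth`.
#' @export
summaryTable <- function(summaries, parameters = NULL) {
  df <- data.frame(method = vapply(summaries, methodId, character(1)),
                   meanError = vapply(summaries, meanError, numeric(1)),
                   ciHalfwidth = vapply(summaries, ciHalfwidth, numeric(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(parameters)) df <- cbind(df[1], parameter = parameters, df[-1])
  df
}

#' Select a tone-curve parameter by cross-validation
#'
#' Stratified k-fold cross-validation over the candidate values: each
#' candidate's curve is applied to the data, the classifier is trained on
#' k-1 folds and scored on the held-out fold, and the candidate with the
#' smallest average error is returned; ties go to the smaller parameter
#' value. All candidates share the same folds.
#'
#' @param candidates numeric vector of candidate `t` or `gamma` values.
#' @param dataset a [LabeledDataset-class].
#' @param curveType tone-curve type whose parameter is selected.
#' @param classifier a [ClassifierSpec-class].
#' @param folds 3 or 5.
#' @param seed integer seed for the fold assignment and per-fold training.
#' @return List with `best` (the selected value) and `table` (data.frame of
#'   candidate vs cross-validated mean error).
#' @export
selectParameter <- function(candidates, dataset, curveType, classifier,
                            folds = 5L, seed = 1L) {
  if (length(candidates) == 0L) .stopf("no candidate parameter values given")
  if (!folds %in% c(3L, 5L)) .stopf("folds must be 3 or 5")
  stopifnot(is(dataset, "LabeledDataset"), is(classifier, "ClassifierSpec"))
  type <- .parseCurveType(curveType)
  n <- nImages(dataset)
  seeds <- .spawnSeeds(seed, folds + 1L)
  set.seed(seeds[folds + 1L])
  fold <- integer(n)
  for (cl in ROI_CLASSES) {
    idx <- which(roiLabels(dataset) == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cvError <- vapply(candidates, function(v) {
    corrected <- applyCurve(dataset, .curveWithParam(type, v, fmaxLevel(dataset)))
    errs <- vapply(seq_len(folds), function(k) {
      te <- which(fold == k)
      pred <- fitPredict(classifier, corrected[-te], corrected[te],
                         seed = seeds[k])
      100 * mean(pred != roiLabels(corrected)[te])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- candidates[order(cvError, candidates)[1]]
  list(best = best,
       table = data.frame(candidate = candidates, cvMeanError = cvError))
}

#' Compare two methods evaluated on identical splits
#'
#' Paired two-sided t-test on the per-trial error differences. Refuses to
#' pair summaries with different split hashes; set `paired = FALSE` for an
#' unpaired Welch test across differing splits. Degenerate cases are handled
#' explicitly: identical per-trial errors give `p = 1`; constant nonzero
#' differences (zero variance) are reported with `p = 0` and an infinite
#' statistic as a documented sentinel, since the t statistic diverges.
#'
#' @param a,b [EvalSummary-class] objects with equal trial counts.
#' @param paired use the paired test (default; requires equal split hashes).
#' @return List with `meanDiff` (mean of `a - b`, percentage points),
#'   `statistic`, `df`, `pValue`, and `paired`.
#' @export
compareMethods <- function(a, b, paired = TRUE) {
  stopifnot(is(a, "EvalSummary"), is(b, "EvalSummary"))
  if (length(a@perTrial) != length(b@perTrial)) {
    .stopf("summaries have different trial counts (%d vs %d)",
           length(a@perTrial), length(b@perTrial))
  }
  if (paired && !identical(a@splitHash, b@splitHash)) {
    .stopf(paste0("split hashes differ (%s vs %s): summaries were not built ",
                  "on identical splits; rerun with shared HoldoutSplits or ",
                  "use paired = FALSE for an unpaired Welch test"),
           a@splitHash, b@splitHash)
  }
  if (paired) {
    d <- a@perTrial - b@perTrial
    n <- length(d)
    if (all(d == 0)) {
      return(list(meanDiff = 0, statistic = 0, df = n - 1, pValue = 1,
                  paired = TRUE))
    }
    if (stats::sd(d) == 0) {
      return(list(meanDiff = mean(d), statistic = sign(mean(d)) * Inf,
                  df = n - 1, pValue = 0, paired = TRUE))
    }
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    list(meanDiff = mean(d), statistic = tstat, df = n - 1,
         pValue = 2 * stats::pt(-abs(tstat), df = n - 1), paired = TRUE)
  } else {
    ht <- stats::t.test(a@perTrial, b@perTrial, paired = FALSE)
    list(meanDiff = mean(a@perTrial) - mean(b@perTrial),
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         pValue = ht$p.value, paired = FALSE)
  }
}
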