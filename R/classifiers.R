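#' Classifier specifications for the holdout harness
#'
#' `ClassifierSpec` is the virtual parent of everything [fitPredict()] can
#' run: the shallow CNN, the classical pixel-vector baselines, and function
#' stubs used to exercise the evaluation machinery with known error
#' behaviour.
#'
#' @name ClassifierSpec-class
#' @aliases ClassifierSpec
#' @export
setClass("ClassifierSpec", representation("VIRTUAL"))

#' CNNClassifier: run the shallow CNN inside the harness
#'
#' @slot config a [CNNConfig-class].
#' @slot epochs,batchSize optional overrides applied at fit time (`NA` keeps
#'   the config values); the harness passes its own per-trial seed.
#' @seealso [cnnClassifier()]
#' @export
setClass("CNNClassifier", contains = "ClassifierSpec",
         representation(config = "CNNConfig", epochs = "integer",
                        batchSize = "integer"))

#' @describeIn fitPredict-methods construct a CNN classifier spec
#' @param config a [CNNConfig-class].
#' @param epochs,batchSize optional training-schedule overrides.
#' @export
cnnClassifier <- function(config = cnnConfig(), epochs = NA, batchSize = NA) {
  new("CNNClassifier", config = config, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize))
}

#' BaselineSpec: a classical classifier on flattened pixel vectors
#'
#' The methods of the comparison study: k-nearest-neighbour (Euclidean
#' distance, majority vote), linear-kernel SVM (C = 1, no feature scaling
#' beyond the shared `[0, 1]` intensity division), LDA (pooled covariance;
#' falls back to a ridge-regularized pooled covariance when the standard fit
#' fails, as it may with 1024 features and 400 samples) and random forest
#' with 100 trees. All consume the identical flattened feature matrix, so
#' performance differences are attributable to the classifier.
#'
#' @slot method one of `"kNN"`, `"SVM"`, `"LDA"`, `"RF"`.
#' @slot k neighbours for kNN (odd, >= 1).
#' @slot nTrees trees for RF (>= 1).
#' @seealso [baselineSpec()], [flattenFeatures()]
#' @export
setClass("BaselineSpec", contains = "ClassifierSpec",
         representation(method = "character", k = "integer", nTrees = "integer"))

setValidity("BaselineSpec", function(object) {
  if (!object@method %in% c("kNN", "SVM", "LDA", "RF")) {
    return("method must be one of kNN, SVM, LDA, RF")
  }
  if (object@method == "kNN" && (object@k < 1L || object@k %% 2L == 0L)) {
    return("k must be odd and >= 1")
  }
  if (object@method == "RF" && object@nTrees < 1L) return("nTrees must be >= 1")
  TRUE
})

#' @describeIn fitPredict-methods construct a classical baseline spec
#' @param method `"kNN"`, `"SVM"`, `"LDA"` or `"RF"`.
#' @param k kNN neighbour count (odd).
#' @param nTrees random-forest tree count.
#' @export
baselineSpec <- function(method = c("kNN", "SVM", "LDA", "RF"), k = 1L,
                         nTrees = 100L) {
  new("BaselineSpec", method = match.arg(method), k = as.integer(k),
      nTrees = as.integer(nTrees))
}

#' StubClassifier: a deterministic stand-in for harness tests
#'
#' Wraps a function `(train, test) -> factor of predicted labels`; used to
#' exercise the holdout machinery with classifiers of known error behaviour
#' (constant prediction, label oracle, intensity thresholds).
#'
#' @slot fun the prediction function.
#' @slot label short description used in summaries.
#' @seealso [stubClassifier()], [constantClassifier()], [oracleClassifier()]
#' @export
setClass("StubClassifier", contains = "ClassifierSpec",
         representation(fun = "function", label = "character"))

#' @describeIn fitPredict-methods wrap an arbitrary prediction function
#' @param fun function of `(train, test)` returning predicted labels.
#' @param label description string.
#' @export
stubClassifier <- function(fun, label = "stub") {
  new("StubClassifier", fun = fun, label = label)
}

#' @describeIn fitPredict-methods stub always predicting one class
#' @param predictLabel the class to predict (`"normal"` or `"cirrhosis"`).
#' @export
constantClassifier <- function(predictLabel = "cirrhosis") {
  predictLabel <- match.arg(predictLabel, ROI_CLASSES)
  stubClassifier(function(train, test) {
    factor(rep(predictLabel, nImages(test)), levels = ROI_CLASSES)
  }, label = sprintf("always-%s", predictLabel))
}

#' @describeIn fitPredict-methods stub returning the true test labels
#' @export
oracleClassifier <- function() {
  stubClassifier(function(train, test) roiLabels(test), label = "oracle")
}

#' @describeIn fitPredict-methods stub predicting `cirrhosis` when the mean
#'   image intensity exceeds `cut`
#' @param cut intensity threshold.
#' @export
meanThresholdClassifier <- function(cut) {
  force(cut)
  stubClassifier(function(train, test) {
    m <- apply(test@images, 3, mean)
    factor(ifelse(m > cut, "cirrhosis", "normal"), levels = ROI_CLASSES)
  }, label = sprintf("mean>%g", cut))
}

#' Flatten ROI images into a feature matrix
#'
#' Each `side x side` image becomes one row of `side^2` pixel features in
#' row-major order: pixel `(r, c)` (1-based, origin top-left) maps to column
#' `(r - 1) * side + c`. Intensities are divided by `fmax` so the baselines
#' see the same `[0, 1]` input contract as the CNN.
#'
#' @param dataset a [LabeledDataset-class].
#' @return List with `features` (n x side^2 numeric matrix, rownames = ids)
#'   and `labels` (factor).
#' @export
flattenFeatures <- function(dataset) {
  stopifnot(is(dataset, "LabeledDataset"))
  side <- imageSide(dataset)
  n <- nImages(dataset)
  x <- matrix(aperm(dataset@images, c(2, 1, 3)), nrow = n, ncol = side * side,
              byrow = TRUE) / fmaxLevel(dataset)
  rownames(x) <- roiIds(dataset)
  list(features = x, labels = roiLabels(dataset))
}

# Ridge-regularized pooled-covariance LDA used when MASS::lda cannot fit
# (singular pooled covariance). Classifies by the linear discriminant
# delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k with
# S = pooled covariance + lambda * mean(diag) * I.
.ridgeLDA <- function(xtr, ytr, xte, lambda = 1e-3) {
  classes <- levels(ytr)
  p <- ncol(xtr)
  n <- nrow(xtr)
  mus <- lapply(classes, function(cl) colMeans(xtr[ytr == cl, , drop = FALSE]))
  sw <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    xc <- sweep(xtr[ytr == classes[i], , drop = FALSE], 2, mus[[i]])
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (n - length(classes))
  diag(sw) <- diag(sw) + lambda * mean(diag(sw))
  sinv <- solve(sw)
  scores <- vapply(seq_along(classes), function(i) {
    a <- sinv %*% mus[[i]]
    drop(xte %*% a) - drop(crossprod(mus[[i]], a)) / 2 +
      log(mean(ytr == classes[i]))
  }, numeric(nrow(xte)))
  factor(classes[max.col(as.matrix(scores), ties.method = "first")],
         levels = classes)
}

#' Fit-and-predict methods
#'
#' @name fitPredict-methods
#' @rdname fitPredict-methods
NULL

.checkPair <- function(train, test) {
  if (nImages(train) == 0L) .stopf("training set is empty")
  if (imageSide(train) != imageSide(test) || fmaxLevel(train) != fmaxLevel(test)) {
    .stopf("train and test must share image side and fmax")
  }
}

#' @rdname fitPredict-methods
#' @param spec,train,test,seed see [fitPredict()].
#' @export
setMethod("fitPredict", "CNNClassifier", function(spec, train, test, seed = 1L) {
  .checkPair(train, test)
  fit <- trainCNN(spec@config, train, seed = seed,
                  epochs = if (is.na(spec@epochs)) NULL else spec@epochs,
                  batchSize = if (is.na(spec@batchSize)) NULL else spec@batchSize)
  predict(fit, test)$class
})

#' @rdname fitPredict-methods
#' @export
setMethod("fitPredict", "BaselineSpec", function(spec, train, test, seed = 1L) {
  .checkPair(train, test)
  tr <- flattenFeatures(train)
  te <- flattenFeatures(test)
  if (spec@method == "LDA" && nlevels(droplevels(tr$labels)) < 2L) {
    .stopf("LDA requires both classes in the training set")
  }
  set.seed(as.integer(seed))
  pred <- switch(spec@method,
    kNN = class::knn(tr$features, te$features, tr$labels, k = spec@k),
    SVM = {
      fit <- e1071::svm(tr$features, tr$labels, kernel = "linear", cost = 1,
                        scale = FALSE)
      predict(fit, te$features)
    },
    LDA = tryCatch({
      fit <- suppressWarnings(MASS::lda(tr$features, grouping = tr$labels))
      predict(fit, te$features)$class
    }, error = function(e) .ridgeLDA(tr$features, tr$labels, te$features)),
    RF = {
      fit <- randomForest::randomForest(tr$features, tr$labels,
                                        ntree = spec@nTrees)
      predict(fit, te$features)
    })
  factor(as.character(pred), levels = ROI_CLASSES)
})

#' @rdname fitPredict-methods
#' @export
setMethod("fitPredict", "StubClassifier", function(spec, train, test, seed = 1L) {
  pred <- spec@fun(train, test)
  if (length(pred) != nImages(test)) {
    .stopf("stub returned %d predictions for %d test images",
           length(pred), nImages(test))
  }
  factor(as.character(pred), levels = ROI_CLASSES)
})

#' Short identifier used in result tables
#' @param spec a classifier spec.
#' @return Character scalar, e.g. `"CNN"`, `"3-NN"`, `"RF"`.
#' @export
classifierLabel <- function(spec) {
  if (is(spec, "CNNClassifier")) return("CNN")
  if (is(spec, "StubClassifier")) return(spec@label)
  switch(spec@method, kNN = sprintf("%d-NN", spec@k), spec@method)
}
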