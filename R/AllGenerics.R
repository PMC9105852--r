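#' @import methods
NULL

#' Maximum representable grey level
#'
#' @param x a [GreyImage-class], [ToneCurve-class], [LookupTable-class] or
#'   [LabeledDataset-class] object.
#' @return Integer scalar, e.g. 255 for 8-bit data, 4095 for 12-bit data.
#' @export
setGeneric("fmaxLevel", function(x) standardGeneric("fmaxLevel"))

#' Pixel matrix of a grey-level image
#'
#' @param x a [GreyImage-class].
#' @return Integer matrix (rows = image rows, origin top-left).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Evaluate a tone curve at given input grey levels
#'
#' @param curve a [ToneCurve-class].
#' @param f integer vector of input grey levels in `[0, fmaxLevel(curve)]`.
#' @return Integer vector of output grey levels (formula evaluated in real
#'   arithmetic, rounded half away from zero, clipped to `[0, fmax]`).
#' @export
setGeneric("evaluateCurve", function(curve, f) standardGeneric("evaluateCurve"))

#' Compile a tone curve into a lookup table
#'
#' @param curve a [ToneCurve-class].
#' @return a [LookupTable-class] with `fmax + 1` entries.
#' @export
setGeneric("buildLUT", function(curve) standardGeneric("buildLUT"))

#' Entries of a lookup table
#'
#' @param x a [LookupTable-class].
#' @return Integer vector of length `fmax + 1`; entry `i` is the output level
#'   for input level `i - 1`.
#' @export
setGeneric("lutEntries", function(x) standardGeneric("lutEntries"))

#' Apply a tone curve to an image or dataset
#'
#' The curve is compiled to a lookup table once and applied pixel-wise.
#' The input object is not modified.
#'
#' @param x a [GreyImage-class] or [LabeledDataset-class]; its `fmax` must
#'   equal the curve's.
#' @param curve a [ToneCurve-class].
#' @return An object of the same class as `x` with transformed pixels.
#' @export
setGeneric("applyCurve", function(x, curve) standardGeneric("applyCurve"))

#' Class labels of a labelled ROI dataset
#'
#' @param x a [LabeledDataset-class].
#' @return Factor with levels `normal`, `cirrhosis`.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' Stable per-image identifiers
#'
#' @param x a [LabeledDataset-class].
#' @return Character vector of unique ids.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' Number of images in a dataset
#'
#' @param x a [LabeledDataset-class].
#' @return Integer scalar.
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' Side length of the square ROI images
#'
#' @param x a [LabeledDataset-class].
#' @return Integer scalar (pixels).
#' @export
setGeneric("imageSide", function(x) standardGeneric("imageSide"))

#' Extract one image from a dataset
#'
#' @param x a [LabeledDataset-class].
#' @param i index.
#' @return a [GreyImage-class].
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' Fit a classifier on a training set and predict a test set
#'
#' The single entry point the holdout harness uses for every classifier, so
#' the CNN, the classical baselines and test stubs are interchangeable.
#'
#' @param spec a classifier specification ([CNNClassifier-class],
#'   [BaselineSpec-class] or [StubClassifier-class]).
#' @param train,test [LabeledDataset-class] objects sharing size and fmax.
#' @param seed integer seed for any stochastic component (weight
#'   initialization, dropout, bootstrap resampling, tie breaking).
#' @return Factor of predicted labels for `test`, levels `normal`/`cirrhosis`.
#' @export
setGeneric("fitPredict", function(spec, train, test, seed = 1L) standardGeneric("fitPredict"))

#' @rdname EvalSummary-class
#' @param x an [EvalSummary-class].
#' @export
setGeneric("perTrialErrors", function(x) standardGeneric("perTrialErrors"))

#' @rdname EvalSummary-class
#' @export
setGeneric("meanError", function(x) standardGeneric("meanError"))

#' @rdname EvalSummary-class
#' @export
setGeneric("ciHalfwidth", function(x) standardGeneric("ciHalfwidth"))

#' @rdname EvalSummary-class
#' @export
setGeneric("splitHash", function(x) standardGeneric("splitHash"))

#' @rdname EvalSummary-class
#' @export
setGeneric("methodId", function(x) standardGeneric("methodId"))
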