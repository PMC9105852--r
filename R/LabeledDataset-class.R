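#' LabeledDataset: ROI images with binary class labels
#'
#' A collection of square single-channel ROI images sharing one side length
#' and one `fmax`, each carrying a class label (`normal` or `cirrhosis`) and a
#' stable identifier. Images are stored as a `side x side x n` integer array.
#'
#' @slot images integer array `side x side x n`.
#' @slot labels factor of length `n`, levels `normal`, `cirrhosis`.
#' @slot ids character vector of `n` unique identifiers.
#' @slot fmax integer maximum grey level.
#'
#' @seealso [labeledDataset()], [generateDataset()], [loadDataset()]
#' @export
setClass("LabeledDataset",
         representation(images = "array", labels = "factor",
                        ids = "character", fmax = "integer"))

#' Class labels used throughout the package
#' @export
ROI_CLASSES <- c("normal", "cirrhosis")

setValidity("LabeledDataset", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a 3-D array (side x side x n)")
  if (d[1] != d[2]) return(sprintf("images must be square, got %dx%d", d[1], d[2]))
  n <- d[3]
  if (length(object@labels) != n || length(object@ids) != n) {
    return(sprintf("images (%d), labels (%d) and ids (%d) must have equal length",
                   n, length(object@labels), length(object@ids)))
  }
  if (!identical(levels(object@labels), ROI_CLASSES)) {
    return("labels must be a factor with levels normal, cirrhosis")
  }
  if (anyNA(object@labels)) return("labels contain NA")
  if (anyDuplicated(object@ids)) {
    return(sprintf("duplicate ids: %s",
                   paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  }
  if (!.isValidFmax(object@fmax)) {
    return(sprintf("fmax must be 2^b - 1, got %s", object@fmax))
  }
  if (n > 0 && (min(object@images) < 0L || max(object@images) > object@fmax)) {
    return(sprintf("pixel values must lie in [0, %d]", object@fmax))
  }
  TRUE
})

#' Construct a labelled ROI dataset
#'
#' @param images integer array `side x side x n`, or a list of equally sized
#'   [GreyImage-class] objects.
#' @param labels character or factor of class labels (`normal`/`cirrhosis`).
#' @param ids character identifiers; defaults to `label_index`.
#' @param fmax maximum grey level (default 255; taken from the images when a
#'   list of GreyImage is given).
#' @return a [LabeledDataset-class].
#' @export
labeledDataset <- function(images, labels, ids = NULL, fmax = 255L) {
  if (is.list(images)) {
    stopifnot(length(images) > 0, all(vapply(images, is, TRUE, "GreyImage")))
    fmax <- fmaxLevel(images[[1]])
    arr <- vapply(images, pixels, pixels(images[[1]]))
  } else {
    arr <- images
  }
  storage.mode(arr) <- "integer"
  labels <- factor(as.character(labels), levels = ROI_CLASSES)
  if (is.null(ids)) {
    ids <- sprintf("%s_%03d", labels, stats::ave(seq_along(labels), labels, FUN = seq_along))
  }
  new("LabeledDataset", images = arr, labels = labels,
      ids = as.character(ids), fmax = as.integer(fmax))
}

#' @export
setMethod("nImages", "LabeledDataset", function(x) dim(x@images)[3])

#' @export
setMethod("imageSide", "LabeledDataset", function(x) dim(x@images)[1])

#' @export
setMethod("fmaxLevel", "LabeledDataset", function(x) x@fmax)

#' @export
setMethod("roiLabels", "LabeledDataset", function(x) x@labels)

#' @export
setMethod("roiIds", "LabeledDataset", function(x) x@ids)

#' @export
setMethod("getImage", "LabeledDataset", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1, i <= nImages(x))
  greyImage(x@images[, , i], x@fmax)
})

#' Subset a dataset by image index
#' @param x a [LabeledDataset-class].
#' @param i integer or logical index over images.
#' @return a [LabeledDataset-class].
#' @export
setMethod("[", "LabeledDataset", function(x, i) {
  new("LabeledDataset", images = x@images[, , i, drop = FALSE],
      labels = x@labels[i], ids = x@ids[i], fmax = x@fmax)
})

#' Per-class image counts
#' @param x a [LabeledDataset-class].
#' @return Named integer vector over `normal`, `cirrhosis`.
#' @export
classCounts <- function(x) {
  stopifnot(is(x, "LabeledDataset"))
  table(x@labels)
}

setMethod("show", "LabeledDataset", function(object) {
  cc <- classCounts(object)
  cat(sprintf("LabeledDataset: %d ROI images %dx%d, fmax=%d (%s)\n",
              nImages(object), imageSide(object), imageSide(object), object@fmax,
              paste(sprintf("%d %s", cc, names(cc)), collapse = ", ")))
})

#' @export
setMethod("applyCurve", signature("LabeledDataset", "ToneCurve"), function(x, curve) {
  if (x@fmax != curve@fmax) {
    .stopf("dataset fmax (%d) does not match curve fmax (%d)", x@fmax, curve@fmax)
  }
  lut <- lutEntries(buildLUT(curve))
  out <- x@images
  out[] <- lut[x@images + 1L]
  new("LabeledDataset", images = out, labels = x@labels, ids = x@ids, fmax = x@fmax)
})
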