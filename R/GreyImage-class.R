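#' GreyImage: a single-channel integer-intensity image
#'
#' The unit every tone-curve operator transforms: a 2-D grid of non-negative
#' integer grey levels together with the maximum representable level `fmax`
#' (255 for 8-bit data, 4095 for 12-bit). Row/column indices follow R matrix
#' convention with the origin at the top-left.
#'
#' @slot pixels integer matrix, all values in `[0, fmax]`.
#' @slot fmax integer, of the form `2^b - 1`.
#'
#' @seealso [greyImage()], [applyCurve()], [readGreyImage()]
#' @export
setClass("GreyImage", representation(pixels = "matrix", fmax = "integer"))

setValidity("GreyImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (anyNA(p)) return("pixels contain NA")
  if (!.isWholeNumber(p)) return("pixels must be whole numbers")
  if (!.isValidFmax(object@fmax)) {
    return(sprintf("fmax must be 2^b - 1 for a positive integer b, got %s", object@fmax))
  }
  if (min(p) < 0 || max(p) > object@fmax) {
    return(sprintf("pixel values must lie in [0, %d]; found range [%s, %s]",
                   object@fmax, min(p), max(p)))
  }
  TRUE
})

#' Construct a GreyImage
#'
#' @param pixels numeric or integer matrix of grey levels.
#' @param fmax maximum representable grey level (default 255, i.e. 8-bit).
#' @return a [GreyImage-class].
#' @examples
#' img <- greyImage(matrix(0:255, 16, 16))
#' fmaxLevel(img)
#' @export
greyImage <- function(pixels, fmax = 255L) {
  pm <- as.matrix(pixels)
  storage.mode(pm) <- "integer"
  new("GreyImage", pixels = pm, fmax = as.integer(fmax))
}

#' @describeIn greyImage pixel matrix accessor
#' @param x a GreyImage.
#' @export
setMethod("pixels", "GreyImage", function(x) x@pixels)

#' @describeIn greyImage maximum grey level accessor
#' @export
setMethod("fmaxLevel", "GreyImage", function(x) x@fmax)

#' @export
setMethod("dim", "GreyImage", function(x) dim(x@pixels))

setMethod("show", "GreyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GreyImage %dx%d, fmax=%d, intensity range [%d, %d]\n",
              d[1], d[2], object@fmax, min(object@pixels), max(object@pixels)))
})
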