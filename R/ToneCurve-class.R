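#' ToneCurve: a grey-level transfer function specification
#'
#' Eight operator types map an input grey level `f` in `[0, fmax]` to an
#' output level `g`:
#'
#' * **type 0** identity: `g = f`
#' * **type I** thresholded line: `g = 0` for `f < t`, else `f`
#' * **type II** contrast-stretching line: `g = 0` for `f < t`,
#'   else `fmax (f - t) / (fmax - t)`
#' * **type III** gamma curve: `g = fmax (f / fmax)^(1/gamma)`
#' * **type IV** inversion: `g = fmax - f`
#' * **type V** thresholded inversion: `g = fmax - f` for `f < t`, else 0
#' * **type VI** steepened inversion: `g = fmax (1 - f/t)` for `f < t`, else 0
#' * **type VII** inverse gamma curve: `g = fmax ((fmax - f)/fmax)^(1/gamma)`
#'
#' Types I-III raise contrast on the light end (dark regions below `t` are
#' blacked out); types IV-VII do the same after inverting intensities, so
#' originally dark regions carry the contrast. Threshold comparisons are
#' strict (`f < t`); `f == t` takes the "otherwise" branch. Outputs are
#' computed in real arithmetic, rounded half away from zero and clipped to
#' `[0, fmax]`.
#'
#' Parameter domains: types I and V accept `0 <= t <= fmax`; type II requires
#' `t <= fmax - 1` (the stretch denominator `fmax - t` must be nonzero);
#' type VI requires `t >= 1` (it divides by `t`); types III and VII require
#' `gamma > 0`.
#'
#' @slot type integer 0-7.
#' @slot t integer threshold (types I, II, V, VI; `NA` otherwise).
#' @slot gamma positive real (types III, VII; `NA` otherwise).
#' @slot fmax integer maximum grey level.
#'
#' @seealso [toneCurve()], [buildLUT()], [applyCurve()]
#' @export
setClass("ToneCurve",
         representation(type = "integer", t = "integer",
                        gamma = "numeric", fmax = "integer"))

.CURVE_ROMAN <- c("0", "I", "II", "III", "IV", "V", "VI", "VII")
.T_TYPES <- c(1L, 2L, 5L, 6L)
.GAMMA_TYPES <- c(3L, 7L)

.parseCurveType <- function(type) {
  if (is.character(type)) {
    if (grepl("^[0-7]$", type)) return(as.integer(type))
    idx <- match(toupper(type), .CURVE_ROMAN)
    if (is.na(idx)) .stopf("unknown curve type '%s' (use 0-7 or 0, I, ..., VII)", type)
    return(idx - 1L)
  }
  as.integer(type)
}

setValidity("ToneCurve", function(object) {
  ty <- object@type
  if (length(ty) != 1L || is.na(ty) || ty < 0L || ty > 7L) {
    return("curve type must be a single integer in 0..7")
  }
  if (!.isValidFmax(object@fmax)) {
    return(sprintf("fmax must be 2^b - 1 for a positive integer b, got %s", object@fmax))
  }
  fmax <- object@fmax
  roman <- .CURVE_ROMAN[ty + 1L]
  if (ty %in% .T_TYPES) {
    t <- object@t
    if (length(t) != 1L || is.na(t)) {
      return(sprintf("type %s requires an integer threshold t", roman))
    }
    lo <- if (ty == 6L) 1L else 0L
    hi <- if (ty == 2L) fmax - 1L else fmax
    if (t < lo || t > hi) {
      return(sprintf("type %s requires %d <= t <= %d, got t=%d", roman, lo, hi, t))
    }
  } else if (!is.na(object@t)) {
    return(sprintf("type %s takes no threshold t", roman))
  }
  if (ty %in% .GAMMA_TYPES) {
    g <- object@gamma
    if (length(g) != 1L || is.na(g) || g <= 0) {
      return(sprintf("type %s requires gamma > 0", roman))
    }
  } else if (!is.na(object@gamma)) {
    return(sprintf("type %s takes no gamma", roman))
  }
  TRUE
})

#' Construct a tone-curve specification
#'
#' @param type curve type: integer 0-7 or roman label `"0"`, `"I"`, ...,
#'   `"VII"`.
#' @param t integer threshold grey level (types I, II, V, VI).
#' @param gamma positive real non-linearity parameter (types III, VII).
#' @param fmax maximum grey level (default 255).
#' @return a [ToneCurve-class].
#' @examples
#' toneCurve("II", t = 20)
#' toneCurve("VI", t = 200)
#' toneCurve(3, gamma = 1/2)
#' @export
toneCurve <- function(type, t = NA, gamma = NA, fmax = 255L) {
  new("ToneCurve", type = .parseCurveType(type), t = as.integer(t),
      gamma = as.numeric(gamma), fmax = as.integer(fmax))
}

#' @describeIn toneCurve curve type as integer 0-7
#' @param x a ToneCurve.
#' @export
curveType <- function(x) x@type

#' @describeIn toneCurve the active parameter (`t`, `gamma`, or `NA` for
#'   parameter-free types)
#' @export
curveParam <- function(x) {
  if (x@type %in% .T_TYPES) return(as.numeric(x@t))
  if (x@type %in% .GAMMA_TYPES) return(x@gamma)
  NA_real_
}

#' @describeIn toneCurve human-readable label, e.g. `"VI(t=200)"`
#' @export
curveLabel <- function(x) {
  roman <- .CURVE_ROMAN[x@type + 1L]
  if (x@type %in% .T_TYPES) return(sprintf("%s(t=%d)", roman, x@t))
  if (x@type %in% .GAMMA_TYPES) return(sprintf("%s(gamma=%g)", roman, x@gamma))
  roman
}

#' @export
setMethod("fmaxLevel", "ToneCurve", function(x) x@fmax)

setMethod("show", "ToneCurve", function(object) {
  cat(sprintf("ToneCurve type %s, fmax=%d\n", curveLabel(object), object@fmax))
})

#' LookupTable: a compiled tone curve
#'
#' Precomputed output level for each of the `fmax + 1` possible input levels;
#' applying a curve to an image is then a single table lookup per pixel.
#'
#' @slot entries integer vector of length `fmax + 1`, values in `[0, fmax]`.
#' @slot fmax integer.
#' @seealso [buildLUT()]
#' @export
setClass("LookupTable", representation(entries = "integer", fmax = "integer"))

setValidity("LookupTable", function(object) {
  if (length(object@entries) != object@fmax + 1L) {
    return(sprintf("lookup table must have fmax + 1 = %d entries, got %d",
                   object@fmax + 1L, length(object@entries)))
  }
  if (anyNA(object@entries)) return("lookup table entries contain NA")
  if (min(object@entries) < 0L || max(object@entries) > object@fmax) {
    return(sprintf("lookup table entries must lie in [0, %d]", object@fmax))
  }
  TRUE
})

#' @export
setMethod("lutEntries", "LookupTable", function(x) x@entries)

#' @export
setMethod("fmaxLevel", "LookupTable", function(x) x@fmax)

#' @export
setMethod("length", "LookupTable", function(x) length(x@entries))

setMethod("show", "LookupTable", function(object) {
  cat(sprintf("LookupTable with %d entries, fmax=%d\n",
              length(object@entries), object@fmax))
})

# Real-arithmetic evaluation of the transfer function, before rounding.
.curveFormula <- function(curve, f) {
  fmax <- as.numeric(curve@fmax)
  t <- as.numeric(curve@t)
  g <- curve@gamma
  switch(as.character(curve@type),
    "0" = f,
    "1" = ifelse(f < t, 0, f),
    "2" = ifelse(f < t, 0, fmax * (f - t) / (fmax - t)),
    "3" = fmax * (f / fmax)^(1 / g),
    "4" = fmax - f,
    "5" = ifelse(f < t, fmax - f, 0),
    "6" = ifelse(f < t, fmax * (1 - f / t), 0),
    "7" = fmax * ((fmax - f) / fmax)^(1 / g))
}

#' @export
setMethod("evaluateCurve", "ToneCurve", function(curve, f) {
  validObject(curve)
  if (anyNA(f) || any(f < 0) || any(f > curve@fmax)) {
    .stopf("input grey levels must lie in [0, %d]", curve@fmax)
  }
  as.integer(.clipGrey(.roundHalfAway(.curveFormula(curve, as.numeric(f))), curve@fmax))
})

#' @export
setMethod("buildLUT", "ToneCurve", function(curve) {
  new("LookupTable", entries = evaluateCurve(curve, 0:curve@fmax), fmax = curve@fmax)
})

#' @export
setMethod("applyCurve", signature("GreyImage", "ToneCurve"), function(x, curve) {
  if (x@fmax != curve@fmax) {
    .stopf("image fmax (%d) does not match curve fmax (%d)", x@fmax, curve@fmax)
  }
  lut <- lutEntries(buildLUT(curve))
  out <- x@pixels
  out[] <- lut[x@pixels + 1L]
  new("GreyImage", pixels = out, fmax = x@fmax)
})
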