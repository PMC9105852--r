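#' SyntheticConfig: parameters of the speckle ROI generator
#'
#' Describes a two-class population of synthetic B-mode-style ROI patches.
#' Each ROI is `clip(round(classMean * S))` where `S` is a unit-mean
#' multiplicative speckle field: an i.i.d. Rayleigh field scaled to mean 1,
#' smoothed with a Gaussian kernel of width `correlationSigma` pixels, whose
#' deviation from 1 is then amplified by `speckleScale` (and floored at 0).
#' `speckleScale -> 0` is the noiseless limit; with `correlationSigma = 1`
#' the default `speckleScale = 2` gives a per-pixel coefficient of variation
#' of roughly 0.3.
#'
#' The cirrhosis class is given a higher mean echo intensity than the normal
#' class (cirrhotic parenchyma appears slightly lighter in B-mode imaging);
#' by default the two classes differ in mean only, with identical texture.
#'
#' @slot nNormal,nCirrhosis image counts (defaults 200 and 300).
#' @slot size ROI side length in pixels (default 32).
#' @slot fmax maximum grey level (default 255).
#' @slot muNormal,muCirrhosis class mean echo intensities (defaults 90, 110).
#' @slot speckleScale amplification of the unit-mean speckle deviation
#'   (default 2; > 0 required, values near 0 are nearly noiseless).
#' @slot correlationSigma Gaussian smoothing sigma in pixels controlling the
#'   speckle grain size (default 1; 0 disables smoothing). May be a vector of
#'   two (normal, cirrhosis) to give the classes different texture; scalar by
#'   default so the classes differ in mean only.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticConfig()], [generateDataset()], [generateROI()]
#' @export
setClass("SyntheticConfig",
         representation(nNormal = "integer", nCirrhosis = "integer",
                        size = "integer", fmax = "integer",
                        muNormal = "numeric", muCirrhosis = "numeric",
                        speckleScale = "numeric", correlationSigma = "numeric",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nNormal < 1L || object@nCirrhosis < 1L) return("class counts must be >= 1")
  if (object@size < 1L) return("size must be >= 1")
  if (!.isValidFmax(object@fmax)) return("fmax must be 2^b - 1")
  for (mu in c(object@muNormal, object@muCirrhosis)) {
    if (!(mu > 0 && mu <= object@fmax)) {
      return(sprintf("class means must lie in (0, %d]", object@fmax))
    }
  }
  if (!(object@speckleScale > 0)) return("speckleScale must be > 0")
  if (!(length(object@correlationSigma) %in% 1:2) || any(object@correlationSigma < 0)) {
    return("correlationSigma must be one or two values >= 0")
  }
  TRUE
})

#' Configure the synthetic speckle ROI generator
#'
#' Defaults emulate the study population the package targets: 200 normal and
#' 300 cirrhosis 32x32 8-bit ROIs, cirrhosis slightly lighter than normal.
#'
#' @param nNormal,nCirrhosis per-class image counts.
#' @param size ROI side length in pixels.
#' @param fmax maximum grey level.
#' @param muNormal,muCirrhosis class mean intensities.
#' @param speckleScale speckle deviation amplification (> 0).
#' @param correlationSigma speckle grain smoothing sigma, pixels (length 1,
#'   or 2 for class-specific texture).
#' @param seed RNG seed.
#' @return a [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(seed = 7)
#' ds <- generateDataset(cfg)
#' classCounts(ds)
#' @export
syntheticConfig <- function(nNormal = 200L, nCirrhosis = 300L, size = 32L,
                            fmax = 255L, muNormal = 90, muCirrhosis = 110,
                            speckleScale = 2, correlationSigma = 1, seed = 1L) {
  new("SyntheticConfig", nNormal = as.integer(nNormal),
      nCirrhosis = as.integer(nCirrhosis), size = as.integer(size),
      fmax = as.integer(fmax), muNormal = as.numeric(muNormal),
      muCirrhosis = as.numeric(muCirrhosis),
      speckleScale = as.numeric(speckleScale),
      correlationSigma = as.numeric(correlationSigma), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d normal (mu=%g) + %d cirrhosis (mu=%g), ",
                     "%dx%d, fmax=%d, speckleScale=%g, correlationSigma=%s, seed=%d\n"),
              object@nNormal, object@muNormal, object@nCirrhosis, object@muCirrhosis,
              object@size, object@size, object@fmax, object@speckleScale,
              paste(object@correlationSigma, collapse = "/"), object@seed))
})

# Separable Gaussian smoothing with edge renormalization (kernel weights are
# renormalized over the in-image support, so a constant field stays constant).
.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1d <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    wt <- numeric(n)
    for (j in -r:r) {
      w <- k[j + r + 1L]
      src <- (1:n) + j
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + w * x[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + w
    }
    out / wt
  }
  t(smooth1d(t(smooth1d(m))))
}

# One unit-mean speckle field of side `size`, drawn from the current RNG.
.speckleField <- function(size, speckleScale, correlationSigma) {
  # Rayleigh(1) via inverse CDF, scaled to unit mean.
  raw <- sqrt(-2 * log(stats::runif(size * size))) / sqrt(pi / 2)
  s0 <- .gaussSmooth(matrix(raw, size, size), correlationSigma)
  pmax(0, 1 + speckleScale * (s0 - 1))
}

.sigmaForClass <- function(config, label) {
  cs <- config@correlationSigma
  if (length(cs) == 1L) return(cs)
  cs[match(label, ROI_CLASSES)]
}

#' Generate one synthetic speckle ROI
#'
#' Draws from the current RNG stream unless `seed` is given, so repeated
#' calls inside [generateDataset()] produce independent fields.
#'
#' @param classMean mean echo intensity of the ROI's class.
#' @param config a [SyntheticConfig-class].
#' @param seed optional integer; when given, the RNG is seeded first so the
#'   call is a pure function of `(classMean, config, seed)`.
#' @param correlationSigma smoothing sigma override (internal use for
#'   class-specific texture); defaults to the config's first value.
#' @return a [GreyImage-class] of side `config@size`.
#' @export
generateROI <- function(classMean, config, seed = NULL, correlationSigma = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cs <- if (is.null(correlationSigma)) config@correlationSigma[1] else correlationSigma
  s <- .speckleField(config@size, config@speckleScale, cs)
  g <- .clipGrey(.roundHalfAway(classMean * s), config@fmax)
  greyImage(matrix(as.integer(g), config@size, config@size), config@fmax)
}

#' Generate a full labelled synthetic dataset
#'
#' Deterministic in `config@seed`: identical configs yield identical pixels.
#' Normal-class images are generated first, then cirrhosis.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [LabeledDataset-class] with `nNormal + nCirrhosis` images.
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nNormal + config@nCirrhosis
  labels <- factor(rep(ROI_CLASSES, c(config@nNormal, config@nCirrhosis)),
                   levels = ROI_CLASSES)
  mus <- c(normal = config@muNormal, cirrhosis = config@muCirrhosis)
  arr <- array(0L, c(config@size, config@size, n))
  for (i in seq_len(n)) {
    lab <- as.character(labels[i])
    arr[, , i] <- pixels(generateROI(mus[[lab]], config,
                                     correlationSigma = .sigmaForClass(config, lab)))
  }
  ids <- sprintf("%s_%03d", labels, stats::ave(seq_len(n), labels, FUN = seq_along))
  new("LabeledDataset", images = arr, labels = labels, ids = ids,
      fmax = config@fmax)
}
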