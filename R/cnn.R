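#' CNNConfig: architecture and training hyperparameters of the shallow CNN
#'
#' The network is two convolution blocks (3x3 kernels, same-size padding,
#' ReLU, 2x2 max-pooling) of `convFilters` filters each, so a 32-pixel input
#' shrinks 32 -> 16 -> 8 and flattens to `convFilters * 8 * 8 = 2048`
#' features, followed by a fully connected 2048-100-2 classifier: a
#' `hiddenUnits` ReLU layer, dropout, and a softmax output over the two
#' classes. Training minimizes cross-entropy with ADAM.
#'
#' @slot inputSide input image side, pixels (default 32; must be divisible
#'   by `poolSide^nBlocks`).
#' @slot convFilters filters per convolution block (default 32).
#' @slot kernelSide,poolSide,nBlocks fixed at 3, 2, 2 (the implemented
#'   architecture family).
#' @slot flattenWidth expected flattened width; must equal
#'   `convFilters * (inputSide / 4)^2` (default 2048).
#' @slot hiddenUnits width of the hidden dense layer (default 100).
#' @slot nClasses number of output classes (fixed at 2).
#' @slot dropoutRate dropout probability on the hidden layer (default 0.5).
#' @slot batchSize mini-batch size (default 400 = one full training set).
#' @slot epochs training epochs (default 100).
#' @slot learningRate ADAM step size (default 0.001; moments 0.9/0.999).
#' @slot seed RNG seed for weight init, shuffling and dropout.
#'
#' @seealso [cnnConfig()], [buildCNN()], [trainCNN()]
#' @export
setClass("CNNConfig",
         representation(inputSide = "integer", convFilters = "integer",
                        kernelSide = "integer", poolSide = "integer",
                        nBlocks = "integer", flattenWidth = "integer",
                        hiddenUnits = "integer", nClasses = "integer",
                        dropoutRate = "numeric", batchSize = "integer",
                        epochs = "integer", learningRate = "numeric",
                        seed = "integer"))

setValidity("CNNConfig", function(object) {
  if (object@kernelSide != 3L || object@poolSide != 2L || object@nBlocks != 2L) {
    return("the implemented architecture family has kernelSide=3, poolSide=2, nBlocks=2")
  }
  red <- object@poolSide^object@nBlocks
  if (object@inputSide < red || object@inputSide %% red != 0L) {
    return(sprintf("inputSide must be a positive multiple of %d", red))
  }
  want <- object@convFilters * (object@inputSide %/% red)^2
  if (object@flattenWidth != want) {
    return(sprintf("flattenWidth must equal convFilters * (inputSide/%d)^2 = %d, got %d",
                   red, want, object@flattenWidth))
  }
  if (object@convFilters < 1L || object@hiddenUnits < 1L) {
    return("convFilters and hiddenUnits must be >= 1")
  }
  if (object@nClasses != 2L) return("nClasses must be 2 (normal vs cirrhosis)")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    return("dropoutRate must lie in [0, 1)")
  }
  if (object@batchSize < 1L || object@epochs < 1L) return("batchSize and epochs must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  TRUE
})

#' Configure the shallow CNN
#'
#' @param inputSide input image side in pixels.
#' @param convFilters filters per convolution block.
#' @param flattenWidth expected flattened width (consistency check against
#'   `convFilters * (inputSide/4)^2`; defaults to that product for the
#'   canonical 32-pixel input).
#' @param hiddenUnits hidden dense layer width.
#' @param dropoutRate dropout probability on the hidden layer.
#' @param batchSize mini-batch size.
#' @param epochs training epochs.
#' @param learningRate ADAM step size.
#' @param seed integer RNG seed.
#' @return a [CNNConfig-class].
#' @examples
#' cfg <- cnnConfig()
#' buildCNN(cfg)
#' @export
cnnConfig <- function(inputSide = 32L, convFilters = 32L, flattenWidth = 2048L,
                      hiddenUnits = 100L, dropoutRate = 0.5, batchSize = 400L,
                      epochs = 100L, learningRate = 0.001, seed = 1L) {
  new("CNNConfig", inputSide = as.integer(inputSide),
      convFilters = as.integer(convFilters), kernelSide = 3L, poolSide = 2L,
      nBlocks = 2L, flattenWidth = as.integer(flattenWidth),
      hiddenUnits = as.integer(hiddenUnits), nClasses = 2L,
      dropoutRate = as.numeric(dropoutRate), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), learningRate = as.numeric(learningRate),
      seed = as.integer(seed))
}

#' CNNModel: a validated, untrained network architecture
#'
#' @slot config the [CNNConfig-class].
#' @slot layers data.frame describing each layer's output shape.
#' @seealso [buildCNN()]
#' @export
setClass("CNNModel", representation(config = "CNNConfig", layers = "data.frame"))

#' Build (and validate) the CNN architecture
#'
#' Checks the configuration's shape arithmetic and returns the layer table;
#' weights are initialized at training time from the seed.
#'
#' @param config a [CNNConfig-class].
#' @return a [CNNModel-class].
#' @export
buildCNN <- function(config) {
  validObject(config)
  s <- config@inputSide
  cf <- config@convFilters
  layers <- data.frame(
    layer = c("input", "conv1+relu", "maxpool1", "conv2+relu", "maxpool2",
              "flatten", "dense+relu", "dropout", "dense+softmax"),
    shape = c(sprintf("%dx%dx1", s, s),
              sprintf("%dx%dx%d", s, s, cf),
              sprintf("%dx%dx%d", s / 2, s / 2, cf),
              sprintf("%dx%dx%d", s / 2, s / 2, cf),
              sprintf("%dx%dx%d", s / 4, s / 4, cf),
              sprintf("%d", config@flattenWidth),
              sprintf("%d", config@hiddenUnits),
              sprintf("%d", config@hiddenUnits),
              sprintf("%d", config@nClasses)),
    stringsAsFactors = FALSE)
  new("CNNModel", config = config, layers = layers)
}

#' @describeIn buildCNN flattened feature width of the architecture
#' @param model a [CNNModel-class].
#' @export
flattenWidth <- function(model) model@config@flattenWidth

setMethod("show", "CNNModel", function(object) {
  cat("Shallow CNN architecture:\n")
  for (i in seq_len(nrow(object@layers))) {
    cat(sprintf("  %-14s %s\n", object@layers$layer[i], object@layers$shape[i]))
  }
  cat(sprintf("  ADAM lr=%g, dropout=%g, batch=%d, epochs=%d\n",
              object@config@learningRate, object@config@dropoutRate,
              object@config@batchSize, object@config@epochs))
})

#' TrainedCNN: a fitted network
#'
#' @slot model the [CNNModel-class] that was trained.
#' @slot weights list of weight matrices and bias vectors.
#' @slot history data.frame with per-epoch training `loss` and `accuracy`.
#' @slot fmax the grey scale the model was trained on (inputs are divided by
#'   it before the first layer).
#' @seealso [trainCNN()], [predict,TrainedCNN-method]
#' @export
setClass("TrainedCNN",
         representation(model = "CNNModel", weights = "list",
                        history = "data.frame", fmax = "integer"))

setMethod("show", "TrainedCNN", function(object) {
  h <- object@history
  cat(sprintf("TrainedCNN: %d epochs, final training loss %.4f, accuracy %.3f\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
})

.datasetCube <- function(dataset, fmax) {
  arr <- dataset@images
  storage.mode(arr) <- "double"
  arr / fmax
}

#' Train the shallow CNN
#'
#' Pixel intensities are scaled to `[0, 1]` by division by the dataset's
#' `fmax` before the first layer (so tone-curve corrections change the
#' network's input distribution, which is exactly the effect under study,
#' while raw bit depth does not). Training is deterministic in `seed`.
#'
#' @param model a [CNNModel-class] or [CNNConfig-class].
#' @param train a [LabeledDataset-class]; image side must match the config.
#' @param seed optional seed overriding the config's (used by the holdout
#'   harness to give every trial its own stream).
#' @param epochs,batchSize optional overrides of the config values.
#' @return a [TrainedCNN-class].
#' @export
trainCNN <- function(model, train, seed = NULL, epochs = NULL, batchSize = NULL) {
  if (is(model, "CNNConfig")) model <- buildCNN(model)
  stopifnot(is(model, "CNNModel"), is(train, "LabeledDataset"))
  cfg <- model@config
  if (nImages(train) == 0L) .stopf("training set is empty")
  if (imageSide(train) != cfg@inputSide) {
    .stopf("image side %d does not match configured input side %d",
           imageSide(train), cfg@inputSide)
  }
  seed <- if (is.null(seed)) cfg@seed else as.integer(seed)
  epochs <- if (is.null(epochs)) cfg@epochs else as.integer(epochs)
  batchSize <- if (is.null(batchSize)) cfg@batchSize else as.integer(batchSize)
  fit <- cnn_train_cpp(.datasetCube(train, fmaxLevel(train)),
                       as.integer(roiLabels(train)) - 1L,
                       cfg@convFilters, cfg@hiddenUnits, cfg@nClasses,
                       cfg@learningRate, cfg@dropoutRate, batchSize, epochs,
                       seed)
  new("TrainedCNN", model = model,
      weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
      history = data.frame(epoch = seq_len(epochs), loss = fit$loss,
                           accuracy = fit$accuracy),
      fmax = fmaxLevel(train))
}

#' @describeIn trainCNN per-epoch training history
#' @param object a [TrainedCNN-class].
#' @export
trainingHistory <- function(object) object@history

#' Predict class labels and probabilities for new ROI images
#'
#' @param object a [TrainedCNN-class].
#' @param newdata a [LabeledDataset-class] or a `side x side x n` array with
#'   the same side and grey scale the model was trained on.
#' @return List with `class` (factor, levels `normal`/`cirrhosis`) and
#'   `prob` (n x 2 matrix of softmax probabilities, columns named by class).
#' @export
setMethod("predict", "TrainedCNN", function(object, newdata) {
  if (is(newdata, "LabeledDataset")) {
    if (fmaxLevel(newdata) != object@fmax) {
      .stopf("dataset fmax (%d) does not match the model's training fmax (%d)",
             fmaxLevel(newdata), object@fmax)
    }
    cube <- .datasetCube(newdata, object@fmax)
  } else {
    arr <- newdata
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    storage.mode(arr) <- "double"
    cube <- arr / object@fmax
  }
  if (dim(cube)[1] != object@model@config@inputSide) {
    .stopf("image side %d does not match the trained input side %d",
           dim(cube)[1], object@model@config@inputSide)
  }
  prob <- cnn_predict_cpp(object@weights, cube)
  colnames(prob) <- ROI_CLASSES
  cls <- factor(ROI_CLASSES[max.col(prob, ties.method = "first")],
                levels = ROI_CLASSES)
  list(class = cls, prob = prob)
})
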