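#' Model configuration for the GAF identification network
#'
#' The architecture follows the tuned-VGG19 pattern: a two-block
#' convolutional stem (two 3x3 convolutions and a max-pool, repeated twice),
#' a core of `coreConvLayers` 3x3 convolutions with `coreFilters` filters
#' and ReLU activations, max pooling followed by global average pooling,
#' dropout, a ReLU dense layer, a second dropout, and a softmax dense layer
#' sized to the number of enrolled users.
#'
#' Two profiles are provided. `"full"` mirrors the reference network
#' (128 px input, 64/128 stem, five conv-512 core, Adam at 1e-5). `"desk"`
#' preserves the architecture's shape at workstation cost (64 px input,
#' 8/16 stem, five conv-32 core, Adam at 1e-3) and is the profile every
#' packaged experiment uses.
#'
#' @param profile `"desk"` or `"full"`; sets the defaults below.
#' @param numClasses number N of enrolled users (>= 2).
#' @param inputSize image side length in pixels; must be a multiple of 8,
#'   >= 16, and equal to the PAA size used at encoding.
#' @param channelMode `"single"` feeds the raw GAF matrix as one channel;
#'   `"replicate3"` maps it to \[0, 1\] and replicates it across 3 channels
#'   (the rendering a pretrained RGB stem expects).
#' @param stemFilters length-2 filter counts of the two stem blocks.
#' @param coreConvLayers,coreFilters core depth and width.
#' @param hiddenUnits width of the first dense layer.
#' @param dropoutCore,dropoutHead dropout fractions after global average
#'   pooling and between the dense layers.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs,patience early stopping: stop after `patience` epochs
#'   without validation-loss improvement, restoring the best epoch.
#' @param augmentShift train-time circular-shift augmentation. Shifting the
#'   encoded window by s samples permutes the GASF's rows and columns by
#'   the same rotation, so each training image is presented at a random
#'   beat phase — the dominant nuisance in non-beat-aligned windows.
#'   Exact (no interpolation), label-preserving, seeded, applied to
#'   training batches only. Default: on for the desk profile, off for the
#'   full profile (which mirrors the reference training protocol).
#' @param ttaShifts inference counterpart of `augmentShift`: average the
#'   softmax probabilities over this many evenly spaced circular shifts of
#'   each probe image (0 disables). Deterministic. Off by default in both
#'   profiles.
#' @param usePretrainedStem initialise the stem from externally supplied
#'   weights (`stemWeightsPath`); off by default — there is no bundled
#'   download, and all packaged experiments use seeded random init.
#' @param stemWeightsPath RDS file holding stem weight matrices.
#' @param seed initialisation seed.
#' @return named list of class `"ModelConfig"`.
#' @export
modelConfig <- function(profile = c("desk", "full"), numClasses = 10L,
                        inputSize = NULL, channelMode = NULL,
                        stemFilters = NULL, coreConvLayers = 5L,
                        coreFilters = NULL, hiddenUnits = NULL,
                        dropoutCore = 0.25, dropoutHead = 0.10,
                        learningRate = NULL, batchSize = 32L,
                        maxEpochs = 40L, patience = 6L, augmentShift = NULL,
                        ttaShifts = NULL, usePretrainedStem = FALSE,
                        stemWeightsPath = NULL, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") {
    list(inputSize = 64L, channelMode = "single", stemFilters = c(8L, 16L),
         coreFilters = 32L, hiddenUnits = 64L, learningRate = 1e-3,
         augmentShift = TRUE, ttaShifts = 0L)
  } else {
    list(inputSize = 128L, channelMode = "replicate3",
         stemFilters = c(64L, 128L), coreFilters = 512L,
         hiddenUnits = 256L, learningRate = 1e-5, augmentShift = FALSE,
         ttaShifts = 0L)
  }
  augmentShift <- isTRUE(augmentShift %||% defaults$augmentShift)
  ttaShifts <- as.integer(ttaShifts %||% defaults$ttaShifts)
  if (ttaShifts < 0) stop("ttaShifts must be non-negative")
  inputSize <- as.integer(inputSize %||% defaults$inputSize)
  channelMode <- match.arg(channelMode %||% defaults$channelMode,
                           c("single", "replicate3"))
  stemFilters <- as.integer(stemFilters %||% defaults$stemFilters)
  coreFilters <- as.integer(coreFilters %||% defaults$coreFilters)
  hiddenUnits <- as.integer(hiddenUnits %||% defaults$hiddenUnits)
  learningRate <- learningRate %||% defaults$learningRate

  if (numClasses < 2L) stop("numClasses must be at least 2")
  if (inputSize < 16L || inputSize %% 8L != 0L)
    stop("inputSize must be a multiple of 8 and >= 16 (three pooling stages)")
  if (length(stemFilters) != 2L) stop("stemFilters must have length 2")
  if (dropoutCore < 0 || dropoutCore >= 1 || dropoutHead < 0 || dropoutHead >= 1)
    stop("dropout fractions must lie in [0, 1)")
  if (learningRate <= 0) stop("learningRate must be positive")

  structure(list(
    profile = profile, numClasses = as.integer(numClasses),
    inputSize = inputSize, channelMode = channelMode,
    channels = if (channelMode == "replicate3") 3L else 1L,
    stemFilters = stemFilters, coreConvLayers = as.integer(coreConvLayers),
    coreFilters = coreFilters, coreKernel = 3L, hiddenUnits = hiddenUnits,
    dropoutCore = dropoutCore, dropoutHead = dropoutHead,
    optimizer = "adam", learningRate = learningRate,
    batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
    patience = as.integer(patience), augmentShift = augmentShift,
    ttaShifts = ttaShifts,
    usePretrainedStem = isTRUE(usePretrainedStem),
    stemWeightsPath = stemWeightsPath, seed = as.integer(seed)),
    class = c("ModelConfig", "list"))
}

#' Build (initialise) a GAFNet model
#'
#' Allocates and seeds all weight tensors (He-normal initialisation). When
#' `usePretrainedStem` is set, the four stem convolution weight matrices
#' are loaded from `stemWeightsPath` instead.
#'
#' @param config a [modelConfig()].
#' @param classes enrolled class labels, in output-unit order; defaults to
#'   `"C1"..."CN"` and is normally overwritten by [trainModel()].
#' @return an untrained [GAFNet-class].
#' @export
buildModel <- function(config, classes = NULL) {
  stopifnot(inherits(config, "ModelConfig"))
  weights <- .cnnInit(config, config$seed)
  if (config$usePretrainedStem) {
    if (is.null(config$stemWeightsPath) || !file.exists(config$stemWeightsPath))
      stop("usePretrainedStem requires an existing stemWeightsPath; ",
           "no pretrained weights are bundled with the package")
    stem <- readRDS(config$stemWeightsPath)
    for (l in 1:4) {
      if (!all(dim(stem$Wc[[l]]) == dim(weights$Wc[[l]])))
        stop("stem weight dimensions do not match the configured architecture")
      weights$Wc[[l]] <- stem$Wc[[l]]
      weights$bc[[l]] <- stem$bc[[l]]
    }
  }
  if (is.null(classes)) classes <- paste0("C", seq_len(config$numClasses))
  new("GAFNet", config = config, weights = weights,
      classes = as.character(classes),
      history = new("TrainingHistory",
                    epochs = data.frame(epoch = integer(), trainLoss = numeric(),
                                        trainAcc = numeric(), valLoss = numeric(),
                                        valAcc = numeric()),
                    stoppedEpoch = 0L, bestEpoch = 0L))
}

#' Count trainable parameters
#'
#' @param model a [GAFNet-class].
#' @return total number of trainable scalars.
#' @export
numParameters <- function(model) {
  stopifnot(is(model, "GAFNet"))
  w <- model@weights
  sum(vapply(w$Wc, length, numeric(1))) +
    sum(vapply(w$bc, length, numeric(1))) +
    length(w$W1) + length(w$b1) + length(w$W2) + length(w$b2)
}

# GAF stack (n x n x N, values in [-1,1]) -> cube of model inputs
# (n x n x (channels*N)); replicate3 maps to [0,1] and repeats channels
.prepareImages <- function(dataset, config) {
  imgs <- gafImages(dataset)
  d <- dim(imgs)
  if (d[1] != config$inputSize)
    stop(sprintf("images are %dx%d but the model expects %dx%d",
                 d[1], d[2], config$inputSize, config$inputSize))
  n <- d[3]
  if (config$channelMode == "single") return(imgs)
  scaled <- (imgs + 1) / 2
  out <- array(0, dim = c(d[1], d[2], 3L * n))
  for (i in seq_len(max(n, 0))) {
    for (c in 1:3) out[, , 3L * (i - 1L) + c] <- scaled[, , i]
  }
  out
}

.labelsToInt <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("labels outside the enrolled classes: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  as.integer(idx - 1L)
}

#' Train a GAFNet on GAF datasets
#'
#' Optimises softmax cross-entropy with Adam; training stops when the
#' validation loss has not improved for `patience` epochs and the
#' best-epoch weights are restored. Data order, weight initialisation and
#' dropout are all seeded, so a run is bit-reproducible on one device.
#'
#' @param model an untrained (or trained) [GAFNet-class].
#' @param train a [GAFDataset-class] for optimisation.
#' @param val a [GAFDataset-class] monitored for early stopping; its
#'   classes must be a subset of the training classes.
#' @param seed training seed (shuffling + dropout); defaults to the config
#'   seed.
#' @param verbose print per-epoch progress.
#' @return the trained [GAFNet-class] with a filled `history`.
#' @export
trainModel <- function(model, train, val, seed = NULL, verbose = FALSE) {
  stopifnot(is(model, "GAFNet"), is(train, "GAFDataset"),
            is(val, "GAFDataset"))
  validObject(train); validObject(val)
  cfg <- model@config
  classes <- sort(unique(gafLabels(train)))
  if (length(classes) != cfg$numClasses)
    stop(sprintf("training set has %d classes but the model was built for %d",
                 length(classes), cfg$numClasses))
  extra <- setdiff(unique(gafLabels(val)), classes)
  if (length(extra))
    stop("validation classes absent from training set: ",
         paste(extra, collapse = ", "))
  if (is.null(seed)) seed <- cfg$seed
  Xtr <- .prepareImages(train, cfg)
  Xval <- .prepareImages(val, cfg)
  ytr <- .labelsToInt(gafLabels(train), classes)
  yval <- .labelsToInt(gafLabels(val), classes)
  fit <- .cnnTrain(model@weights, cfg, Xtr, ytr, Xval, yval,
                   as.integer(seed), isTRUE(verbose))
  hist <- new("TrainingHistory",
              epochs = data.frame(epoch = seq_along(fit$trainLoss),
                                  trainLoss = fit$trainLoss,
                                  trainAcc = fit$trainAcc,
                                  valLoss = fit$valLoss,
                                  valAcc = fit$valAcc),
              stoppedEpoch = as.integer(fit$stoppedEpoch),
              bestEpoch = as.integer(fit$bestEpoch))
  initialize(model, weights = fit$weights, classes = classes, history = hist)
}

#' Per-class probabilities for a batch of GAF images
#'
#' Deterministic inference (dropout off). Rows sum to 1. When the model
#' config sets `ttaShifts > 0`, probabilities are averaged over that many
#' evenly spaced circular shifts of each image (rows and columns rotated
#' together — exactly the image of the circularly shifted window), which
#' makes the prediction robust to the beat phase of the probe window.
#'
#' @param model a trained [GAFNet-class].
#' @param dataset a [GAFDataset-class] (or bare n x n x N array).
#' @return N x numClasses matrix of class probabilities, columns named by
#'   the enrolled classes.
#' @export
predictProbs <- function(model, dataset) {
  stopifnot(is(model, "GAFNet"))
  if (!is(dataset, "GAFDataset"))
    dataset <- gafDataset(dataset,
                          labels = rep("?", dim(dataset)[3]))
  n <- nImages(dataset)
  if (n == 0L) stop("empty image batch")
  X <- .prepareImages(dataset, model@config)
  tta <- model@config$ttaShifts %||% 0L
  if (tta < 1L) {
    probs <- .cnnPredict(model@weights, model@config, X, n)
  } else {
    side <- dim(X)[1]
    shifts <- unique(round(seq(0, side, length.out = tta + 1L)[-(tta + 1L)]))
    probs <- 0
    for (s in shifts) {
      idx <- ((seq_len(side) - 1L + s) %% side) + 1L
      probs <- probs + .cnnPredict(model@weights, model@config,
                                   X[idx, idx, , drop = FALSE], n)
    }
    probs <- probs / length(shifts)
  }
  colnames(probs) <- model@classes
  probs
}

#' @describeIn predictProbs `predict` method returning probabilities
#'   (`type = "prob"`) or hard labels (`type = "class"`, argmax with ties
#'   broken toward the lowest class index).
#' @param object a trained [GAFNet-class].
#' @param newdata a [GAFDataset-class].
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
setMethod("predict", "GAFNet",
          function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- predictProbs(object, newdata)
  if (type == "prob") return(probs)
  object@classes[apply(probs, 1, which.max)]
})

#' Training history accessor
#'
#' @param model a [GAFNet-class].
#' @return the [TrainingHistory-class].
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "GAFNet"))
  model@history
}
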