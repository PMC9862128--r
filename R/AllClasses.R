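#' @import methods
NULL

.ACTIVITIES <- c("resting", "math", "walking", "running", "handbike", "unknown")

#' ECGRecording: a uniformly sampled single-lead ECG voltage series
#'
#' Container for one single-lead ECG recording: an amplitude series (arbitrary
#' linear units; GAF rescaling removes scale), its sampling rate, and the
#' subject / activity / lead labels used downstream for identification.
#'
#' @slot samples numeric vector of finite amplitudes (length >= 1).
#' @slot samplingRate sampling frequency in Hz (> 0).
#' @slot subjectId opaque subject label.
#' @slot activity one of resting, math, walking, running, handbike, unknown.
#' @slot lead lead name; ambulatory single-lead devices typically record a
#'   modified lead II.
#'
#' @seealso [ecgRecording()] for the user-facing constructor.
#' @export
setClass("ECGRecording",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    subjectId = "character",
    activity = "character",
    lead = "character"
  ),
  prototype(
    subjectId = "unknown",
    activity = "unknown",
    lead = "II-modified"
  )
)

setValidity("ECGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive finite number")
  }
  if (length(object@samples) < 1L) {
    msg <- c(msg, "samples must contain at least one value")
  }
  if (anyNA(object@samples) || any(!is.finite(object@samples))) {
    msg <- c(msg, "samples must all be finite (no NA/NaN/Inf)")
  }
  if (length(object@activity) != 1L || !(object@activity %in% .ACTIVITIES)) {
    msg <- c(msg, sprintf("activity must be one of: %s",
                          paste(.ACTIVITIES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecording
#'
#' @param samples numeric amplitude series (finite, length >= 1).
#' @param samplingRate sampling rate in Hz.
#' @param subjectId subject label.
#' @param activity activity label (see [ECGRecording-class]).
#' @param lead lead name.
#' @return an [ECGRecording-class] object.
#' @examples
#' rec <- ecgRecording(sin(2 * pi * 1.2 * seq(0, 5, by = 1 / 128)), 128)
#' duration(rec)
#' @export
ecgRecording <- function(samples, samplingRate, subjectId = "unknown",
                         activity = "unknown", lead = "II-modified") {
  new("ECGRecording", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      subjectId = as.character(subjectId), activity = as.character(activity),
      lead = as.character(lead))
}

#' ECGSegment: one fixed-length analysis window of a recording
#'
#' @slot samples window amplitudes (finite).
#' @slot samplingRate Hz.
#' @slot subjectId inherited subject label.
#' @slot activity inherited activity label.
#' @slot index ordinal position of the window within its source recording.
#' @export
setClass("ECGSegment",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    subjectId = "character",
    activity = "character",
    index = "integer"
  )
)

setValidity("ECGSegment", function(object) {
  msg <- character()
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "segment samples must be finite")
  if (length(object@index) != 1L || object@index < 1L)
    msg <- c(msg, "index must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' GAFImage: a Gramian Angular Summation Field matrix
#'
#' A square symmetric matrix with entries in [-1, 1], the cosine of the sum
#' of the polar angles of a rescaled time-series window. Its main diagonal
#' satisfies G[i,i] = 2 * xt[i]^2 - 1 where xt is the rescaled series.
#'
#' @slot gram the n x n matrix.
#' @slot mode rescale mode used: "symmetric" ([-1,1]) or "unit" ([0,1]).
#' @slot refSign encoding metadata: sign of the rescaled series at the
#'   reference index (the temporally first largest-magnitude element). The
#'   GASF is invariant under global negation of the series, so in symmetric
#'   mode this one bit is what makes recovery exact rather than
#'   sign-ambiguous; NA when unknown.
#' @slot subjectId provenance: subject label ("" if unknown).
#' @slot activity provenance: activity label.
#' @slot segmentIndex provenance: source window index (NA if unknown).
#' @export
setClass("GAFImage",
  representation(
    gram = "matrix",
    mode = "character",
    refSign = "numeric",
    subjectId = "character",
    activity = "character",
    segmentIndex = "integer"
  ),
  prototype(mode = "symmetric", refSign = NA_real_, subjectId = "",
            activity = "unknown", segmentIndex = NA_integer_)
)

setValidity("GAFImage", function(object) {
  msg <- character()
  g <- object@gram
  if (nrow(g) != ncol(g)) msg <- c(msg, "gram must be square")
  if (length(g) && (anyNA(g) || any(!is.finite(g))))
    msg <- c(msg, "gram entries must be finite")
  if (length(g) && (max(g) > 1 + 1e-9 || min(g) < -1 - 1e-9))
    msg <- c(msg, "gram entries must lie in [-1, 1]")
  if (!object@mode %in% c("symmetric", "unit"))
    msg <- c(msg, "mode must be 'symmetric' or 'unit'")
  if (length(msg)) msg else TRUE
})

#' GAFDataset: a labelled stack of equally sized GAF images
#'
#' The classifier-facing container: an n x n x count array of GASF matrices,
#' one subject label per image, and free-form metadata describing how the
#' stack was produced (window length, PAA size, rescale mode, source).
#'
#' @slot images numeric array of dimension n x n x count.
#' @slot labels character vector, one subject label per image.
#' @slot activities character vector, one activity label per image.
#' @slot meta named list of provenance metadata.
#' @seealso [gafDataset()], [writeGAFDataset()], [splitDataset()]
#' @export
setClass("GAFDataset",
  representation(
    images = "array",
    labels = "character",
    activities = "character",
    meta = "list"
  )
)

setValidity("GAFDataset", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) {
    msg <- c(msg, "images must be a 3-d array (n x n x count)")
  } else {
    if (d[1] != d[2]) msg <- c(msg, "images must be square (dim1 == dim2)")
    if (d[3] != length(object@labels))
      msg <- c(msg, sprintf("label count (%d) must equal image count (%d)",
                            length(object@labels), d[3]))
    if (length(object@activities) &&
        length(object@activities) != length(object@labels))
      msg <- c(msg, "activities must be empty or match label count")
  }
  if (length(object@images) && any(!is.finite(object@images)))
    msg <- c(msg, "image entries must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GAFDataset
#'
#' @param images either a list of [GAFImage-class] objects or an
#'   n x n x count numeric array.
#' @param labels subject label per image; defaults to the images' provenance.
#' @param activities activity label per image; defaults to provenance.
#' @param meta named list of metadata (window seconds, PAA size, mode, ...).
#' @return a [GAFDataset-class].
#' @export
gafDataset <- function(images, labels = NULL, activities = NULL,
                       meta = list()) {
  if (is.list(images)) {
    if (length(images)) {
      stopifnot(all(vapply(images, is, logical(1), "GAFImage")))
      n <- nrow(images[[1]]@gram)
      arr <- array(0, dim = c(n, n, length(images)))
      for (i in seq_along(images)) {
        if (nrow(images[[i]]@gram) != n)
          stop("all images in a GAFDataset must share identical dimensions")
        arr[, , i] <- images[[i]]@gram
      }
      if (is.null(labels))
        labels <- vapply(images, function(im) im@subjectId, character(1))
      if (is.null(activities))
        activities <- vapply(images, function(im) im@activity, character(1))
    } else {
      arr <- array(numeric(0), dim = c(0, 0, 0))
      labels <- character(0)
      activities <- character(0)
    }
    images <- arr
  }
  if (is.null(labels)) stop("labels are required when images is an array")
  if (is.null(activities)) activities <- rep("unknown", length(labels))
  new("GAFDataset", images = images, labels = as.character(labels),
      activities = as.character(activities), meta = meta)
}

#' SubjectParams: a synthetic cardiac identity
#'
#' Per-subject morphology and rhythm parameters of the sum-of-Gaussians beat
#' model: each beat is \eqn{z(\theta) = \sum_k a_k \exp(-(\theta -
#' \theta_k)^2 / (2 b_k^2))} over phase \eqn{\theta \in [-\pi, \pi)}, with
#' one Gaussian per P, Q, R, S, T wave.
#'
#' @slot thetas wave centre phases (radians), strictly increasing P<Q<R<S<T.
#' @slot amps wave amplitudes (arbitrary linear units).
#' @slot widths wave widths (radians, > 0).
#' @slot meanHR mean heart rate, beats/minute, in [30, 220].
#' @slot hrSD beat-to-beat heart-rate standard deviation (bpm, >= 0).
#' @slot jitterSD within-subject per-beat relative jitter of amps/widths.
#' @slot subjectId identity label.
#' @export
setClass("SubjectParams",
  representation(
    thetas = "numeric",
    amps = "numeric",
    widths = "numeric",
    meanHR = "numeric",
    hrSD = "numeric",
    jitterSD = "numeric",
    subjectId = "character"
  )
)

setValidity("SubjectParams", function(object) {
  msg <- character()
  if (length(object@thetas) != 5L || length(object@amps) != 5L ||
      length(object@widths) != 5L)
    msg <- c(msg, "thetas, amps, widths must each have length 5 (P,Q,R,S,T)")
  else {
    if (any(diff(object@thetas) <= 0))
      msg <- c(msg, "wave phases must be strictly increasing (P<Q<R<S<T)")
    if (any(object@thetas <= -pi) || any(object@thetas >= pi))
      msg <- c(msg, "wave phases must lie in (-pi, pi)")
    if (any(object@widths <= 0)) msg <- c(msg, "wave widths must be positive")
  }
  if (object@meanHR < 30 || object@meanHR > 220)
    msg <- c(msg, "meanHR must lie in [30, 220] bpm")
  if (object@hrSD < 0) msg <- c(msg, "hrSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TrainingHistory: per-epoch optimisation record
#'
#' @slot epochs data.frame with columns epoch, trainLoss, trainAcc,
#'   valLoss, valAcc.
#' @slot stoppedEpoch epoch at which training stopped.
#' @slot bestEpoch epoch whose weights were restored (lowest validation loss).
#' @export
setClass("TrainingHistory",
  representation(
    epochs = "data.frame",
    stoppedEpoch = "integer",
    bestEpoch = "integer"
  )
)

setValidity("TrainingHistory", function(object) {
  msg <- character()
  if (length(object@stoppedEpoch) == 1L && length(object@bestEpoch) == 1L &&
      !is.na(object@bestEpoch) && object@bestEpoch > object@stoppedEpoch)
    msg <- c(msg, "bestEpoch cannot exceed stoppedEpoch")
  if (length(msg)) msg else TRUE
})

setOldClass(c("ModelConfig", "list"))

#' GAFNet: the VGG-style convolutional identification model
#'
#' Holds the architecture/training configuration (see [modelConfig()]),
#' the weight tensors, the enrolled class labels and, after training, the
#' optimisation history.
#'
#' @slot config named list produced by [modelConfig()].
#' @slot weights named list of weight matrices/vectors.
#' @slot classes enrolled subject labels, in output-unit order.
#' @slot history a [TrainingHistory-class] (zero-row before training).
#' @seealso [buildModel()], [trainModel()], [predictProbs()]
#' @export
setClass("GAFNet",
  representation(
    config = "list",
    weights = "list",
    classes = "character",
    history = "TrainingHistory"
  )
)

#' EvalReport: closed-set identification scorecard
#'
#' @slot confusion C x C count matrix, rows = true class, cols = predicted.
#' @slot accuracy fraction of probes identified correctly.
#' @slot perClassAccuracy per-class recall.
#' @slot FRR false rejection rate: fraction of genuine probes not accepted
#'   as their own identity.
#' @slot FAR false acceptance rate: macro-average over classes i of the rate
#'   at which probes of other classes are accepted as i.
#' @slot K the ratio FRR / FAR (NA when FAR is 0).
#' @slot threshold rejection threshold on the top softmax probability
#'   (NA = pure argmax).
#' @slot nRejected number of probes rejected by the threshold.
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    perClassAccuracy = "numeric",
    FRR = "numeric",
    FAR = "numeric",
    K = "numeric",
    threshold = "numeric",
    nRejected = "integer"
  ),
  prototype(threshold = NA_real_, nRejected = 0L)
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be non-negative")
  for (nm in c("accuracy", "FRR", "FAR")) {
    v <- slot(object, nm)
    if (length(v) == 1L && !is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})
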