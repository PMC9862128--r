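#' Accessors for gafid classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `ecgSamples()` the amplitude series, `samplingRate()` the rate in Hz,
#' `subjectId()` / `activity()` the labels, `duration()` the length in
#' seconds, `gafImages()` the image array, `gafLabels()` the per-image
#' labels, `nImages()` the image count, and `gramMatrix()` the raw matrix
#' of a single image.
#'
#' @param x an object.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("gafImages", function(x) standardGeneric("gafImages"))
#' @rdname accessors
#' @export
setGeneric("gafLabels", function(x) standardGeneric("gafLabels"))
#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @rdname accessors
#' @export
setGeneric("gramMatrix", function(x) standardGeneric("gramMatrix"))

#' @rdname accessors
setMethod("ecgSamples", "ECGRecording", function(x) x@samples)
#' @rdname accessors
setMethod("ecgSamples", "ECGSegment", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "ECGRecording", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "ECGSegment", function(x) x@samplingRate)
#' @rdname accessors
setMethod("subjectId", "ECGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "ECGSegment", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "SubjectParams", function(x) x@subjectId)
#' @rdname accessors
setMethod("activity", "ECGRecording", function(x) x@activity)
#' @rdname accessors
setMethod("activity", "ECGSegment", function(x) x@activity)
#' @rdname accessors
setMethod("duration", "ECGRecording",
          function(x) length(x@samples) / x@samplingRate)
#' @rdname accessors
setMethod("gafImages", "GAFDataset", function(x) x@images)
#' @rdname accessors
setMethod("gafLabels", "GAFDataset", function(x) x@labels)
#' @rdname accessors
setMethod("nImages", "GAFDataset", function(x) dim(x@images)[3])
#' @rdname accessors
setMethod("gramMatrix", "GAFImage", function(x) x@gram)

setMethod("show", "ECGRecording", function(object) {
  cat(sprintf(
    "ECGRecording: %d samples @ %g Hz (%.2f s)\n  subject: %s  activity: %s  lead: %s\n",
    length(object@samples), object@samplingRate,
    length(object@samples) / object@samplingRate,
    object@subjectId, object@activity, object@lead))
})

setMethod("show", "ECGSegment", function(object) {
  cat(sprintf("ECGSegment #%d: %d samples @ %g Hz  subject: %s  activity: %s\n",
              object@index, length(object@samples), object@samplingRate,
              object@subjectId, object@activity))
})

setMethod("show", "GAFImage", function(object) {
  cat(sprintf("GAFImage: %d x %d (%s mode)  subject: %s\n",
              nrow(object@gram), ncol(object@gram), object@mode,
              ifelse(nzchar(object@subjectId), object@subjectId, "<none>")))
})

setMethod("show", "GAFDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("GAFDataset: %d images of %d x %d, %d subject(s)\n",
              d[3], d[1], d[2], length(unique(object@labels))))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SubjectParams", function(object) {
  cat(sprintf("SubjectParams '%s': meanHR %.1f bpm (sd %.2f)\n",
              object@subjectId, object@meanHR, object@hrSD))
  m <- rbind(theta = object@thetas, amp = object@amps, width = object@widths)
  colnames(m) <- c("P", "Q", "R", "S", "T")
  print(round(m, 3))
})

setMethod("show", "GAFNet", function(object) {
  cat(sprintf("GAFNet: input %dx%d, stem %s, core %dx%d, %d classes (%s)\n",
              object@config$inputSize, object@config$inputSize,
              paste(object@config$stemFilters, collapse = "/"),
              object@config$coreConvLayers, object@config$coreFilters,
              object@config$numClasses,
              if (nrow(object@history@epochs)) "trained" else "untrained"))
  cat(sprintf("  trainable parameters: %s\n",
              format(numParameters(object), big.mark = ",")))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d classes, %d probes\n",
              nrow(object@confusion), sum(object@confusion) + object@nRejected))
  cat(sprintf("  accuracy %.4f  FRR %.5f  FAR %.5f  K %s\n",
              object@accuracy, object@FRR, object@FAR,
              ifelse(is.na(object@K), "NA", sprintf("%.2f", object@K))))
  if (!is.na(object@threshold))
    cat(sprintf("  reject threshold %.3f (%d rejected)\n",
                object@threshold, object@nRejected))
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: stopped at epoch %d, best epoch %d\n",
              object@stoppedEpoch, object@bestEpoch))
  if (nrow(object@epochs)) {
    tail_df <- utils::tail(object@epochs, 3)
    print(tail_df, row.names = FALSE)
  }
})
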