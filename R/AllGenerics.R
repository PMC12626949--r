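#' Accessor generics
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param x an armetry object.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("accelMatrix", function(x) standardGeneric("accelMatrix"))
#' @rdname accessors
#' @export
setGeneric("timeStamps", function(x) standardGeneric("timeStamps"))
#' @rdname accessors
#' @export
setGeneric("limbSide", function(x) standardGeneric("limbSide"))
#' @rdname accessors
#' @export
setGeneric("limbRole", function(x) standardGeneric("limbRole"))
#' @rdname accessors
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))
#' @rdname accessors
#' @export
setGeneric("nAnnotators", function(x) standardGeneric("nAnnotators"))
#' @rdname accessors
#' @export
setGeneric("windowArray", function(x) standardGeneric("windowArray"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("datasetVariant", function(x) standardGeneric("datasetVariant"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setMethod("nSamples", "RawTrace", function(x) length(x@t))
#' @rdname accessors
#' @export
setMethod("nSamples", "LabelTrack", function(x) length(x@labels))
#' @rdname accessors
#' @export
setMethod("nSamples", "WindowedDataset", function(x) dim(x@windows)[1])
#' @rdname accessors
#' @export
setMethod("sampleRate", "RawTrace", function(x) x@rateHz)
#' @rdname accessors
#' @export
setMethod("sampleRate", "LabelTrack", function(x) x@rateHz)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AnnotationSet", function(x) x@frameRateHz)
#' @rdname accessors
#' @export
setMethod("accelMatrix", "RawTrace", function(x) x@a)
#' @rdname accessors
#' @export
setMethod("timeStamps", "RawTrace", function(x) x@t)
#' @rdname accessors
#' @export
setMethod("limbSide", "RawTrace", function(x) x@side)
#' @rdname accessors
#' @export
setMethod("limbRole", "RawTrace", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("labelValues", "LabelTrack", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("nAnnotators", "AnnotationSet", function(x) length(x@tracks))
#' @rdname accessors
#' @export
setMethod("windowArray", "WindowedDataset", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("windowLabels", "WindowedDataset", function(x) x@y)
#' @rdname accessors
#' @export
setMethod("subjectIds", "WindowedDataset", function(x) x@subjectIds)
#' @rdname accessors
#' @export
setMethod("datasetVariant", "WindowedDataset", function(x) x@variant)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "TrainedModel", function(x) x@history)

#' Annotator label tracks
#'
#' @param x an [AnnotationSet-class].
#' @param limb `"left"` or `"right"`.
#' @return list of character label vectors, one per annotator.
#' @export
setGeneric("annotatorTracks", function(x, limb) standardGeneric("annotatorTracks"))

#' @rdname annotatorTracks
#' @export
setMethod("annotatorTracks", "AnnotationSet", function(x, limb) {
  lapply(x@tracks, function(tr) {
    if (is.null(tr[[limb]])) stop("no annotations for limb '", limb, "'")
    tr[[limb]]
  })
})

setMethod("show", "RawTrace", function(object) {
  cat(sprintf("RawTrace: %d samples @ %g Hz (%.1f s), side=%s, role=%s\n",
              nSamples(object), object@rateHz,
              nSamples(object) / object@rateHz, object@side, object@role))
})

setMethod("show", "LabelTrack", function(object) {
  tab <- table(factor(object@labels, levels = LABEL_LEVELS))
  cat(sprintf("LabelTrack: %d samples @ %g Hz | F=%d NF=%d U=%d\n",
              nSamples(object), object@rateHz, tab["F"], tab["NF"], tab["U"]))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d annotator(s), limbs: %s, %d frames @ %g Hz\n",
              nAnnotators(object),
              paste(names(object@tracks[[1]]), collapse = "/"),
              length(object@tracks[[1]][[1]]), object@frameRateHz))
})

setMethod("show", "WindowedDataset", function(object) {
  d <- dim(object@windows)
  cat(sprintf(
    "WindowedDataset (%s): %d windows of %d x %d, %d subjects | F=%d NF=%d\n",
    object@variant, d[1], d[2], d[3], length(unique(object@subjectIds)),
    sum(object@y == 1L), sum(object@y == 0L)))
})

setMethod("show", "TrainedModel", function(object) {
  h <- object@history
  best <- if (nrow(h)) max(h$val_accuracy) else NA_real_
  cat(sprintf(
    "TrainedModel: input %s, %d epochs run, best val accuracy %.4f\n",
    paste(object@spec$inputShape, collapse = "x"), object@epochsRun, best))
})
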