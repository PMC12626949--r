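#' @import methods
NULL

LABEL_LEVELS <- c("F", "NF", "U")

#' RawTrace: one limb's tri-axial acceleration time series
#'
#' Holds timestamped x/y/z acceleration in units of g for a single wrist
#' sensor, together with the nominal sampling rate, the body side the sensor
#' was worn on, and its clinical role (paretic or non-paretic limb).
#'
#' @slot t numeric vector of sample timestamps in seconds, strictly increasing.
#' @slot a numeric matrix with one row per sample and columns \code{x,y,z},
#'   acceleration in g (gravity included; no gravity compensation).
#' @slot rateHz nominal sampling rate in Hz.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot role \code{"paretic"} or \code{"nonparetic"}.
#'
#' @seealso [rawTrace()] for the user constructor, [readAccelCsv()].
#' @exportClass RawTrace
setClass("RawTrace",
  representation(
    t = "numeric", a = "matrix",
    rateHz = "numeric", side = "character", role = "character"
  )
)

setValidity("RawTrace", function(object) {
  msg <- character()
  if (length(object@t) != nrow(object@a))
    msg <- c(msg, "length(t) must equal nrow(a)")
  if (ncol(object@a) != 3L)
    msg <- c(msg, "acceleration matrix must have 3 columns (x, y, z)")
  if (length(object@t) > 1L && any(diff(object@t) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (!object@role %in% c("paretic", "nonparetic"))
    msg <- c(msg, "role must be 'paretic' or 'nonparetic'")
  if (length(msg)) msg else TRUE
})

#' Construct a RawTrace
#'
#' @param t sample timestamps in seconds (strictly increasing).
#' @param a n x 3 matrix of acceleration in g (columns x, y, z).
#' @param rateHz nominal sampling rate in Hz.
#' @param side `"left"` or `"right"`.
#' @param role `"paretic"` or `"nonparetic"`.
#' @return A [RawTrace-class] object.
#' @examples
#' tr <- rawTrace(t = (0:29) / 30, a = cbind(x = rnorm(30, 0, 0.01),
#'   y = rnorm(30, 0, 0.01), z = rnorm(30, 1, 0.01)), rateHz = 30,
#'   side = "right", role = "paretic")
#' nSamples(tr)
#' @export
rawTrace <- function(t, a, rateHz, side, role) {
  a <- as.matrix(a)
  colnames(a) <- c("x", "y", "z")
  new("RawTrace", t = as.numeric(t), a = a, rateHz = as.numeric(rateHz),
      side = side, role = role)
}

#' LabelTrack: per-sample activity class labels on a stated timeline
#'
#' Labels are \code{"F"} (functional), \code{"NF"} (non-functional) or
#' \code{"U"} (unknown), one per sample of a timeline with a fixed rate.
#'
#' @slot rateHz timeline rate in Hz.
#' @slot labels character vector of per-sample labels in \code{F/NF/U}.
#' @exportClass LabelTrack
setClass("LabelTrack", representation(rateHz = "numeric", labels = "character"))

setValidity("LabelTrack", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (length(object@labels) == 0L)
    msg <- c(msg, "labels must be nonempty")
  if (!all(object@labels %in% LABEL_LEVELS))
    msg <- c(msg, "labels must be in {F, NF, U}")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelTrack
#' @param labels character vector with values in `"F"`, `"NF"`, `"U"`.
#' @param rateHz timeline rate in Hz.
#' @return A [LabelTrack-class] object.
#' @export
labelTrack <- function(labels, rateHz) {
  new("LabelTrack", rateHz = as.numeric(rateHz), labels = as.character(labels))
}

#' AnnotationSet: per-annotator, per-limb frame labels
#'
#' The frame-by-frame labels produced by independent annotators reviewing the
#' session video, one label track per annotator per limb.
#'
#' @slot frameRateHz video frame rate in Hz.
#' @slot tracks a list with one element per annotator; each element is a named
#'   list of character label vectors, one per limb (\code{"left"},
#'   \code{"right"}), all of equal length, values in \code{F/NF/U}.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(frameRateHz = "numeric", tracks = "list"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@tracks) < 1L)
    msg <- c(msg, "at least one annotator is required")
  lens <- unlist(lapply(object@tracks, function(tr) vapply(tr, length, 1L)))
  if (length(unique(lens)) > 1L)
    msg <- c(msg, "all annotator tracks must have equal length")
  ok <- all(unlist(lapply(object@tracks, function(tr)
    vapply(tr, function(x) all(x %in% LABEL_LEVELS), TRUE))))
  if (!ok) msg <- c(msg, "annotation labels must be in {F, NF, U}")
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#' @param tracks list (one per annotator) of named lists of per-limb label
#'   vectors, e.g. `list(list(left = ..., right = ...), ...)`.
#' @param frameRateHz video frame rate in Hz.
#' @return An [AnnotationSet-class] object.
#' @export
annotationSet <- function(tracks, frameRateHz) {
  new("AnnotationSet", frameRateHz = as.numeric(frameRateHz), tracks = tracks)
}

#' WindowedDataset: fixed-length labeled windows with provenance
#'
#' The modeling currency of the pipeline: each window is a \code{T x C} slice
#' of (possibly bilateral) accelerometry carrying one binary label
#' (1 = functional, 0 = non-functional). Unknown-labeled samples never reach
#' this container.
#'
#' @slot windows numeric array \code{N x T x C}; \code{C} is 3 for single-arm
#'   variants and 6 for the combined (bilateral) variant.
#' @slot y integer vector of N binary labels (1 = functional).
#' @slot subjectIds character vector of N subject provenance tags.
#' @slot variant \code{"paretic"}, \code{"nonparetic"} or \code{"combined"}.
#' @exportClass WindowedDataset
setClass("WindowedDataset",
  representation(windows = "array", y = "integer",
                 subjectIds = "character", variant = "character"))

setValidity("WindowedDataset", function(object) {
  msg <- character()
  d <- dim(object@windows)
  if (length(d) != 3L)
    msg <- c(msg, "windows must be an N x T x C array")
  else {
    if (d[1] != length(object@y))
      msg <- c(msg, "dim(windows)[1] must equal length(y)")
    if (d[1] != length(object@subjectIds))
      msg <- c(msg, "dim(windows)[1] must equal length(subjectIds)")
    if (object@variant %in% c("paretic", "nonparetic") && d[3] != 3L)
      msg <- c(msg, "single-arm variants must have 3 channels")
    if (object@variant == "combined" && d[3] != 6L)
      msg <- c(msg, "combined variant must have 6 channels")
  }
  if (!all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "labels y must be binary 0/1")
  if (!object@variant %in% c("paretic", "nonparetic", "combined"))
    msg <- c(msg, "variant must be paretic, nonparetic or combined")
  if (length(msg)) msg else TRUE
})

#' Construct a WindowedDataset
#' @param windows numeric array N x T x C.
#' @param y binary labels, 1 = functional.
#' @param subjectIds subject provenance tag per window.
#' @param variant `"paretic"`, `"nonparetic"` or `"combined"`.
#' @return A [WindowedDataset-class] object.
#' @export
windowedDataset <- function(windows, y, subjectIds, variant) {
  if (length(dim(windows)) != 3L) stop("windows must be an N x T x C array")
  new("WindowedDataset", windows = windows, y = as.integer(y),
      subjectIds = as.character(subjectIds), variant = variant)
}

#' TrainedModel: fitted classifier with architecture and history
#'
#' @slot spec the architecture description (see [buildArchitecture()]).
#' @slot weights named list of fitted weight tensors (best-epoch weights when
#'   early stopping restored them).
#' @slot history data.frame with one row per epoch run: loss, accuracy,
#'   val_loss, val_accuracy, lr.
#' @slot epochsRun number of epochs actually run.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(spec = "list", weights = "list",
                 history = "data.frame", epochsRun = "integer"))

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (object@epochsRun > 700L)
    msg <- c(msg, "epochsRun must be <= 700")
  if (nrow(object@history) != object@epochsRun)
    msg <- c(msg, "history must have one row per epoch run")
  if (length(msg)) msg else TRUE
})
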