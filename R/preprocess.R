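#' Down-sample a trace to the 30 Hz analysis rate
#'
#' Traces recorded above 30 Hz are low-pass filtered (4th-order Butterworth,
#' 12 Hz cutoff, zero-phase via forward-backward filtering) to prevent
#' aliasing, then linearly interpolated onto a uniform 30 Hz grid starting at
#' the first original timestamp. A 30 Hz input is returned unchanged.
#'
#' @param trace a [RawTrace-class] with `rateHz >= 30`.
#' @param cutoffHz anti-alias cutoff (must be <= 15 Hz, the output Nyquist).
#' @return A [RawTrace-class] at 30 Hz with `floor(n / rate * 30)` samples.
#' @export
resampleTo30Hz <- function(trace, cutoffHz = 12) {
  stopifnot(is(trace, "RawTrace"))
  rate <- sampleRate(trace)
  if (rate < 30) .stopf("unsupported rate %g Hz: below the 30 Hz target", rate)
  if (cutoffHz > 15) .stopf("cutoffHz must be <= 15 (output Nyquist)")
  if (rate == 30) return(trace)
  t <- timeStamps(trace)
  a <- accelMatrix(trace)
  bf <- signal::butter(4, cutoffHz / (rate / 2), type = "low")
  aF <- apply(a, 2, function(col) signal::filtfilt(bf, col))
  n30 <- floor(nrow(a) / rate * 30)
  tNew <- t[1] + (seq_len(n30) - 1) / 30
  aNew <- apply(aF, 2, function(col) stats::approx(t, col, xout = tNew,
                                                   rule = 2)$y)
  rawTrace(tNew, aNew, 30, limbSide(trace), limbRole(trace))
}

#' Harmonize left/right sensor axes
#'
#' Left- and right-worn sensors see mirrored anatomy; a single axis sign
#' flip makes them comparable. Right-side traces are the reference and pass
#' through unchanged; left-side traces have the configured mirror axis
#' negated. Applying the transform twice restores the original trace.
#'
#' @param trace a [RawTrace-class] with a known side.
#' @param mirrorAxis the axis to negate on left-side traces (default `"x"`).
#' @return The harmonized [RawTrace-class].
#' @export
harmonizeAxes <- function(trace, mirrorAxis = "x") {
  stopifnot(is(trace, "RawTrace"))
  if (!mirrorAxis %in% c("x", "y", "z"))
    .stopf("mirrorAxis must be one of x, y, z")
  if (limbSide(trace) == "right") return(trace)
  a <- accelMatrix(trace)
  a[, mirrorAxis] <- -a[, mirrorAxis]
  rawTrace(timeStamps(trace), a, sampleRate(trace), limbSide(trace),
           limbRole(trace))
}

#' Majority-vote consensus labels across annotators
#'
#' Per frame, the label chosen by a strict majority of annotators; frames
#' with no strict majority become unknown (`"U"`).
#'
#' @param ann an [AnnotationSet-class].
#' @param limb limb to vote over.
#' @return A [LabelTrack-class] at the annotation frame rate.
#' @export
consensusLabels <- function(ann, limb) {
  stopifnot(is(ann, "AnnotationSet"))
  tracks <- annotatorTracks(ann, limb)
  m <- do.call(cbind, tracks)
  a <- ncol(m)
  nF <- rowSums(m == "F")
  nN <- rowSums(m == "NF")
  lab <- rep("U", nrow(m))
  lab[nF > a / 2] <- "F"
  lab[nN > a / 2] <- "NF"
  labelTrack(lab, sampleRate(ann))
}

#' Pairwise inter-annotator agreement
#'
#' Mean over all annotator pairs of the percentage of frames on which the
#' two annotators assign the same label.
#'
#' @param ann an [AnnotationSet-class] with at least 2 annotators.
#' @param limb limb to compare.
#' @return Agreement percentage in `[0, 100]`.
#' @export
annotatorAgreement <- function(ann, limb) {
  stopifnot(is(ann, "AnnotationSet"))
  tracks <- annotatorTracks(ann, limb)
  if (length(tracks) < 2) .stopf("need >= 2 annotators to compute agreement")
  prs <- utils::combn(length(tracks), 2)
  100 * mean(apply(prs, 2, function(pr)
    mean(tracks[[pr[1]]] == tracks[[pr[2]]])))
}

#' Transfer video-frame labels onto the 30 Hz sensor timeline
#'
#' Each 30 Hz sensor sample takes the label of the video frame whose time
#' interval contains the sample's timestamp mapped through the clock map;
#' samples outside the annotated span become unknown (`"U"`).
#'
#' @param track a [LabelTrack-class] on the video timeline.
#' @param map a [clockMap()] relating video and sensor time.
#' @param nSamples30 number of 30 Hz sensor samples to label.
#' @param t0 sensor timestamp of the first sample (default 0).
#' @return A [LabelTrack-class] at 30 Hz of length `nSamples30`.
#' @export
transferLabels <- function(track, map, nSamples30, t0 = 0) {
  stopifnot(is(track, "LabelTrack"))
  lab <- labelValues(track)
  fr <- sampleRate(track)
  tSensor <- t0 + (seq_len(nSamples30) - 1) / 30
  # the 1e-6 guards samples that lie exactly on a frame boundary against
  # floating-point roundoff pushing them into the previous frame
  frame <- floor(sensorToVideo(map, tSensor) * fr + 1e-6) + 1L
  out <- rep("U", nSamples30)
  ok <- frame >= 1L & frame <= length(lab)
  out[ok] <- lab[frame[ok]]
  labelTrack(out, 30)
}

# Core tiler: remove U samples, split what remains into maximal contiguous
# runs, tile each run with non-overlapping windows from its start (trailing
# remainder dropped), label each window by strict majority (ties dropped).
.windowize <- function(a, labels, windowS = 2, rateHz = 30) {
  wlen <- as.integer(round(windowS * rateHz))
  keep <- labels != "U"
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  wins <- list()
  ys <- integer(0)
  for (j in which(runs$values)) {
    runLen <- runs$lengths[j]
    nWin <- runLen %/% wlen
    if (nWin == 0) next
    for (wIdx in seq_len(nWin)) {
      i0 <- starts[j] + (wIdx - 1L) * wlen
      idx <- i0:(i0 + wlen - 1L)
      lab <- .majorityFN(labels[idx])
      if (is.na(lab)) next                        # tied window dropped
      wins[[length(wins) + 1L]] <- a[idx, , drop = FALSE]
      ys <- c(ys, if (lab == "F") 1L else 0L)
    }
  }
  nW <- length(wins)
  X <- array(0, c(nW, wlen, ncol(a)))
  for (i in seq_len(nW)) X[i, , ] <- wins[[i]]
  list(windows = X, y = ys)
}

#' Segment a labeled 30 Hz trace into 2-second windows
#'
#' Unknown-labeled samples are removed first; the remaining data are split
#' into maximal contiguous runs, and each run is tiled with non-overlapping
#' windows from its start, dropping any trailing remainder shorter than a
#' window. Each window's label is the strict majority of its sample labels;
#' tied windows are dropped.
#'
#' @param trace a 30 Hz [RawTrace-class].
#' @param labels a 30 Hz [LabelTrack-class] aligned with `trace`.
#' @param windowS window length in seconds (default 2, i.e. 60 samples).
#' @param subjectId provenance tag for the windows.
#' @param variant dataset variant; defaults to the trace's limb role.
#' @return A [WindowedDataset-class].
#' @export
segmentAndWindow <- function(trace, labels, windowS = 2, subjectId = "s01",
                             variant = NULL) {
  stopifnot(is(trace, "RawTrace"), is(labels, "LabelTrack"))
  if (nSamples(trace) != nSamples(labels))
    .stopf("trace (%d) and labels (%d) must have equal length",
           nSamples(trace), nSamples(labels))
  if (is.null(variant)) variant <- limbRole(trace)
  res <- .windowize(accelMatrix(trace), labelValues(labels), windowS,
                    sampleRate(trace))
  windowedDataset(res$windows, res$y, rep(subjectId, length(res$y)), variant)
}

#' Assemble a dataset variant from both arms
#'
#' The three variants mirror the three ways the data can be organized:
#' `"paretic"` (paretic channels and labels), `"nonparetic"` (non-paretic
#' channels and labels), and `"combined"` (both arms' channels
#' `x1,y1,z1,x2,y2,z2` under the paretic labels, with samples where either
#' arm is unknown removed before windowing — so the combined variant never
#' has more windows than the paretic one).
#'
#' @param paretic,nonparetic lists `list(trace=, labels=)` on a common 30 Hz
#'   timeline.
#' @param variant `"paretic"`, `"nonparetic"` or `"combined"`.
#' @param windowS window length in seconds.
#' @param subjectId provenance tag.
#' @return A [WindowedDataset-class].
#' @export
assembleVariant <- function(paretic, nonparetic, variant, windowS = 2,
                            subjectId = "s01") {
  np <- nSamples(paretic$trace)
  nn <- nSamples(nonparetic$trace)
  if (np != nn || nSamples(paretic$labels) != np ||
      nSamples(nonparetic$labels) != nn)
    .stopf("timeline mismatch: paretic %d vs nonparetic %d samples", np, nn)
  variant <- match.arg(variant, c("paretic", "nonparetic", "combined"))
  if (variant == "paretic")
    return(segmentAndWindow(paretic$trace, paretic$labels, windowS,
                            subjectId, "paretic"))
  if (variant == "nonparetic")
    return(segmentAndWindow(nonparetic$trace, nonparetic$labels, windowS,
                            subjectId, "nonparetic"))
  lab <- labelValues(paretic$labels)
  lab[labelValues(nonparetic$labels) == "U"] <- "U"
  a6 <- cbind(accelMatrix(paretic$trace), accelMatrix(nonparetic$trace))
  res <- .windowize(a6, lab, windowS, sampleRate(paretic$trace))
  windowedDataset(res$windows, res$y, rep(subjectId, length(res$y)),
                  "combined")
}

#' Robust per-channel scaler (median / interquartile range)
#'
#' `fitScaler()` computes, per channel, the median (Q2) and interquartile
#' range (IQR = Q3 - Q1) pooled over all training windows and time steps;
#' `applyScaler()` transforms `X_scaled = (X - Q2) / IQR`. A constant channel
#' (IQR 0) is centered and divided by 1, with a warning. Fit the scaler on
#' the training split only and apply it to both splits.
#'
#' @param x an `N x T x C` window array or a [WindowedDataset-class].
#' @return `fitScaler()` returns a `ScalerParams` list (`median`, `iqr` per
#'   channel); `applyScaler()` returns the transformed array.
#' @export
fitScaler <- function(x) {
  if (is(x, "WindowedDataset")) x <- windowArray(x)
  if (length(dim(x)) != 3L || dim(x)[1] == 0L)
    .stopf("cannot fit scaler: empty or malformed training set")
  C_ <- dim(x)[3]
  med <- numeric(C_)
  iqr <- numeric(C_)
  for (ch in seq_len(C_)) {
    v <- as.vector(x[, , ch])
    med[ch] <- stats::median(v)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr[ch] <- q[2] - q[1]
  }
  if (any(iqr == 0)) {
    warning("constant channel(s) ", paste(which(iqr == 0), collapse = ", "),
            ": IQR is 0, dividing by 1")
    iqr[iqr == 0] <- 1
  }
  structure(list(median = med, iqr = iqr, channels = C_),
            class = "ScalerParams")
}

#' @rdname fitScaler
#' @param params a `ScalerParams` from [fitScaler()].
#' @export
applyScaler <- function(params, x) {
  stopifnot(inherits(params, "ScalerParams"))
  wasDataset <- is(x, "WindowedDataset")
  if (wasDataset) ds <- x
  if (wasDataset) x <- windowArray(x)
  if (dim(x)[3] != params$channels)
    .stopf("scaler has %d channels but data has %d", params$channels,
           dim(x)[3])
  for (ch in seq_len(params$channels))
    x[, , ch] <- (x[, , ch] - params$median[ch]) / params$iqr[ch]
  if (wasDataset)
    return(windowedDataset(x, windowLabels(ds), subjectIds(ds),
                           datasetVariant(ds)))
  x
}
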