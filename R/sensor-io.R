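#' Read a raw accelerometer CSV
#'
#' Reads the fixed CSV dialect `timestamp,x,y,z` (seconds as float,
#' acceleration in units of g) into a validated [RawTrace-class]. Malformed
#' rows (non-numeric fields) are dropped with a message giving their count.
#'
#' @param path CSV file path.
#' @param side `"left"` or `"right"`.
#' @param role `"paretic"` or `"nonparetic"`.
#' @param rateHz nominal sampling rate; inferred from the median timestamp
#'   step when `NULL`.
#' @return A [RawTrace-class].
#' @export
readAccelCsv <- function(path, side, role, rateHz = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dt <- data.table::fread(path, colClasses = "character",
                          showProgress = FALSE)
  need <- c("timestamp", "x", "y", "z")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    .stopf("schema error in %s: missing column(s) %s", path,
           paste(missing, collapse = ", "))
  num <- suppressWarnings(
    lapply(need, function(cl) as.numeric(dt[[cl]])))
  names(num) <- need
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad)) {
    message(sprintf("readAccelCsv: dropped %d malformed row(s) from %s",
                    sum(bad), basename(path)))
    num <- lapply(num, function(v) v[!bad])
  }
  if (length(num$timestamp) > 1 && any(diff(num$timestamp) <= 0))
    .stopf("parse error in %s: timestamps are not strictly increasing", path)
  if (is.null(rateHz))
    rateHz <- round(1 / stats::median(diff(num$timestamp)))
  rawTrace(num$timestamp, cbind(x = num$x, y = num$y, z = num$z),
           rateHz, side, role)
}

#' Write a RawTrace to CSV
#'
#' @param trace a [RawTrace-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeAccelCsv <- function(trace, path) {
  stopifnot(is(trace, "RawTrace"))
  a <- accelMatrix(trace)
  data.table::fwrite(data.table::data.table(
    timestamp = timeStamps(trace), x = a[, 1], y = a[, 2], z = a[, 3]), path)
  invisible(path)
}

#' Read/write annotation CSV (`frame,annotator,limb,label`)
#'
#' One row per video frame per annotator per limb; labels are `F`, `NF`
#' or `U`.
#'
#' @param path CSV path.
#' @param frameRateHz video frame rate.
#' @return [readAnnotationCsv()] returns an [AnnotationSet-class];
#'   [writeAnnotationCsv()] invisibly returns `path`.
#' @export
readAnnotationCsv <- function(path, frameRateHz = 30) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("frame", "annotator", "limb", "label")
  if (length(setdiff(need, names(dt))))
    .stopf("schema error in %s: expected columns %s", path,
           paste(need, collapse = ","))
  anns <- sort(unique(dt$annotator))
  limbs <- unique(dt$limb)
  tracks <- lapply(anns, function(aIdx) {
    tr <- lapply(limbs, function(lb) {
      sub <- dt[dt$annotator == aIdx & dt$limb == lb, ]
      sub$label[order(sub$frame)]
    })
    stats::setNames(tr, limbs)
  })
  annotationSet(tracks, frameRateHz)
}

#' @rdname readAnnotationCsv
#' @param ann an [AnnotationSet-class].
#' @export
writeAnnotationCsv <- function(ann, path) {
  stopifnot(is(ann, "AnnotationSet"))
  rows <- list()
  for (aIdx in seq_len(nAnnotators(ann))) {
    for (lb in names(ann@tracks[[aIdx]])) {
      lab <- ann@tracks[[aIdx]][[lb]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        frame = seq_along(lab) - 1L, annotator = aIdx, limb = lb, label = lab)
    }
  }
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Detect synchronization peaks in the calibration prelude
#'
#' The sensor is oscillated rapidly along z before being attached, producing
#' distinct peaks in the z-axis signal at the oscillation reversal points.
#' The detector looks at the first `searchWindowS` seconds, removes the
#' gravity offset by subtracting the window median, and finds local maxima of
#' the absolute deviation exceeding half of the window maximum, at least
#' `minSeparationS` apart.
#'
#' @param trace a [RawTrace-class] covering the calibration prelude.
#' @param axis axis carrying the oscillation (default `"z"`).
#' @param expected expected number of peaks (default 5).
#' @param searchWindowS prelude search window in seconds.
#' @param minSeparationS minimum peak separation in seconds.
#' @return Numeric vector of exactly `expected` strictly increasing peak
#'   times (seconds); any other count raises a sync-failure error reporting
#'   how many peaks were found.
#' @export
detectSyncPeaks <- function(trace, axis = "z", expected = 5,
                            searchWindowS = 2, minSeparationS = 0.1) {
  stopifnot(is(trace, "RawTrace"))
  t <- timeStamps(trace)
  sel <- t <= t[1] + searchWindowS
  z <- accelMatrix(trace)[sel, axis]
  d <- abs(z - stats::median(z))
  if (length(d) >= 3) {
    # 3-sample moving average: keeps extremum locations of the symmetric
    # oscillation lobes but stops sensor noise splitting one lobe in two
    sm <- as.numeric(stats::filter(d, rep(1 / 3, 3), sides = 2))
    d <- ifelse(is.na(sm), d, sm)
  }
  thr <- 0.5 * max(d)
  found <- numeric(0)
  if (thr > 0) {
    pk <- pracma::findpeaks(d, minpeakheight = thr,
                            minpeakdistance = max(
                              1L, as.integer(round(minSeparationS *
                                                     sampleRate(trace)))))
    if (!is.null(pk)) {
      tSel <- t[sel]
      dt <- 1 / sampleRate(trace)
      found <- sort(vapply(pk[, 2], function(i) {
        # parabolic sub-sample refinement: quantized peak times are too
        # coarse for the short prelude to anchor the clock fit
        if (i > 1 && i < length(d)) {
          den <- d[i - 1] - 2 * d[i] + d[i + 1]
          if (den < 0) {
            off <- 0.5 * (d[i - 1] - d[i + 1]) / den
            return(tSel[i] + max(-0.5, min(0.5, off)) * dt)
          }
        }
        tSel[i]
      }, 1))
    }
  }
  if (length(found) != expected)
    .stopf("sync failure: found %d peak(s), expected %d", length(found),
           expected)
  found
}

#' Clock map between video and sensor time
#'
#' @param offsetS sensor time minus video time at the first sync event.
#' @param scale drift factor (sensor seconds per video second, ~1).
#' @param residualRmsS root-mean-square fit residual in seconds.
#' @return A `ClockMap` list.
#' @export
clockMap <- function(offsetS, scale = 1, residualRmsS = 0) {
  if (scale <= 0.9 || scale >= 1.1)
    .stopf("implausible clock drift: scale %.4f outside (0.9, 1.1)", scale)
  structure(list(offsetS = offsetS, scale = scale,
                 residualRmsS = residualRmsS), class = "ClockMap")
}

#' Align sensor and video clocks from matched sync peaks
#'
#' Least-squares linear map from video time to sensor time,
#' `t_sensor = offset + scale * t_video`, fitted on the matched peak times.
#' Identical lists give the identity map exactly.
#'
#' @param sensorPeaks,videoPeaks equal-length vectors (>= 2) of matched peak
#'   times in seconds.
#' @param maxDrift largest believable clock drift `|scale - 1|`. The sync
#'   peaks span only about a second, so a fitted drift larger than this is
#'   sampling-quantization noise, not clock behavior — extrapolated over a
#'   whole session it would wreck the alignment. Such fits fall back to the
#'   offset-only map (`scale = 1`).
#' @return A [clockMap()] with the fitted offset, scale and residual RMS.
#' @export
alignClocks <- function(sensorPeaks, videoPeaks, maxDrift = 0.005) {
  if (length(sensorPeaks) != length(videoPeaks))
    .stopf("peak lists differ in length (%d vs %d)", length(sensorPeaks),
           length(videoPeaks))
  if (length(sensorPeaks) < 2)
    .stopf("need at least 2 matched peaks, got %d", length(sensorPeaks))
  v <- videoPeaks; s <- sensorPeaks
  vc <- v - mean(v)
  b <- sum(vc * (s - mean(s))) / sum(vc^2)
  if (abs(b - 1) > maxDrift) b <- 1
  a <- mean(s) - b * mean(v)
  resid <- s - (a + b * v)
  clockMap(offsetS = a, scale = b,
           residualRmsS = sqrt(mean(resid^2)))
}

#' Map video-time values to sensor time
#'
#' @param map a [clockMap()].
#' @param videoTimeS video times in seconds.
#' @return Sensor times in seconds.
#' @export
videoToSensor <- function(map, videoTimeS) {
  stopifnot(inherits(map, "ClockMap"))
  map$offsetS + map$scale * videoTimeS
}

#' @rdname videoToSensor
#' @param sensorTimeS sensor times in seconds.
#' @export
sensorToVideo <- function(map, sensorTimeS) {
  stopifnot(inherits(map, "ClockMap"))
  (sensorTimeS - map$offsetS) / map$scale
}
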