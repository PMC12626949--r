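#' Movement profile for synthetic wrist accelerometry
#'
#' Describes the statistical content of one limb's session: how much of the
#' time the arm is used functionally, how that use clusters into bursts, the
#' amplitude of non-functional gait oscillation, sensor noise, and which axis
#' carries gravity at rest.
#'
#' Functional bursts are modeled as smooth (minimum-jerk-like) re-orientations
#' of the gravity vector with superimposed low-frequency movement pulses;
#' non-functional motion is either stillness or sinusoidal gait oscillation.
#'
#' @param functionalFraction proportion of session samples labeled functional,
#'   in `[0, 1]`.
#' @param burstRate nominal functional bursts per minute.
#' @param burstDurationS mean burst duration in seconds.
#' @param gaitAmplitudeG amplitude (g) of non-functional gait oscillation.
#' @param noiseSdG standard deviation (g) of white sensor noise.
#' @param gravityAxis axis carrying +1 g at rest: `"x"`, `"y"` or `"z"`.
#' @param tiltRangeDeg range (degrees) of the gravity re-orientation during
#'   functional bursts; smaller tilts weaken the functional signature and
#'   make the two classes overlap.
#' @return A `MovementProfile` list.
#' @examples
#' movementProfile(functionalFraction = 0.4)
#' @export
movementProfile <- function(functionalFraction = 0.3, burstRate = 4,
                            burstDurationS = 6, gaitAmplitudeG = 0.25,
                            noiseSdG = 0.02, gravityAxis = "z",
                            tiltRangeDeg = c(40, 80)) {
  if (functionalFraction < 0 || functionalFraction > 1)
    .stopf("functionalFraction must be in [0, 1]")
  if (burstDurationS <= 0) .stopf("burstDurationS must be > 0")
  if (any(c(burstRate, gaitAmplitudeG, noiseSdG) < 0))
    .stopf("rates and amplitudes must be >= 0")
  if (!gravityAxis %in% c("x", "y", "z"))
    .stopf("gravityAxis must be one of x, y, z")
  if (length(tiltRangeDeg) != 2 || tiltRangeDeg[1] <= 0 ||
      tiltRangeDeg[2] < tiltRangeDeg[1] || tiltRangeDeg[2] > 90)
    .stopf("tiltRangeDeg must be an increasing pair in (0, 90]")
  structure(list(functionalFraction = functionalFraction,
                 burstRate = burstRate, burstDurationS = burstDurationS,
                 gaitAmplitudeG = gaitAmplitudeG, noiseSdG = noiseSdG,
                 gravityAxis = gravityAxis, tiltRangeDeg = tiltRangeDeg),
            class = "MovementProfile")
}

#' Cohort configuration for the synthetic generator
#'
#' @param nSubjects number of subjects (>= 2 for leave-one-subject-out use).
#' @param ratesHz sampling rates to draw from, a subset of `{30, 50, 200}`.
#' @param sessionMinutes session duration per subject.
#' @param annotators number of independent annotators.
#' @param transitionJitterS half-width (s) of the window around each label
#'   transition within which annotators may disagree.
#' @param seed RNG seed for the whole cohort.
#' @return A `CohortConfig` list.
#' @export
cohortConfig <- function(nSubjects, ratesHz = c(30, 50), sessionMinutes = 10,
                         annotators = 3, transitionJitterS = 0.5, seed = 1) {
  if (!.isCount(nSubjects) || nSubjects < 2)
    .stopf("nSubjects must be a count >= 2 (got %s)", nSubjects)
  if (!all(ratesHz %in% c(30, 50, 200)))
    .stopf("ratesHz must be drawn from {30, 50, 200}")
  if (sessionMinutes <= 0) .stopf("sessionMinutes must be > 0")
  if (!.isCount(annotators) || annotators < 1)
    .stopf("annotators must be a count >= 1")
  structure(list(nSubjects = as.integer(nSubjects), ratesHz = ratesHz,
                 sessionMinutes = sessionMinutes,
                 annotators = as.integer(annotators),
                 transitionJitterS = transitionJitterS,
                 seed = as.integer(seed)), class = "CohortConfig")
}

# Sync prelude: five reversal extrema of a 2 Hz z-axis oscillation (2.5
# cycles over 1.25 s), amplitude 2 g — the "shake before donning" signature.
.SYNC <- list(nOsc = 5L, freqHz = 2, amplitudeG = 2, restGapS = 0.75)

.syncPreludeDurationS <- function(nOsc = .SYNC$nOsc, freqHz = .SYNC$freqHz) {
  nOsc / (2 * freqHz)
}

# Analytic times of the prelude's reversal extrema.
.syncPeakTimes <- function(nOsc = .SYNC$nOsc, freqHz = .SYNC$freqHz) {
  (2 * seq_len(nOsc) - 1) / (4 * freqHz)
}

# Minimum-jerk smoothstep on [0, 1].
.smoothstep <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Rotate unit gravity vector g0 by angle theta toward random direction
# `dirv` (orthogonal to g0); returns length-3 vector per angle.
.tiltGravity <- function(g0, dirv, theta) {
  outer(cos(theta), g0) + outer(sin(theta), dirv)
}

# Build per-sample label + signal content for one limb.
.limbSession <- function(profile, rateHz, minutes) {
  n <- as.integer(round(rateHz * 60 * minutes))
  dt <- 1 / rateHz
  t <- (seq_len(n) - 1L) * dt
  axes <- c(x = 1L, y = 2L, z = 3L)
  gAx <- axes[[profile$gravityAxis]]
  oAx <- setdiff(1:3, gAx)

  a <- matrix(0, n, 3)
  a[, gAx] <- 1                                   # resting gravity
  labels <- rep("NF", n)

  # prelude: large z oscillation while the sensor is shaken
  preN <- as.integer(round(.syncPreludeDurationS() * rateHz))
  preIdx <- seq_len(preN)
  a[preIdx, 3] <- a[preIdx, 3] +
    .SYNC$amplitudeG * sin(2 * pi * .SYNC$freqHz * t[preIdx])

  actStart <- as.integer(round((.syncPreludeDurationS() + .SYNC$restGapS) *
                                 rateHz)) + 1L
  nAct <- n - actStart + 1L

  targetF <- round(profile$functionalFraction * n)
  if (targetF > nAct) targetF <- nAct
  segs <- list()                                  # (startIdx, len, kind)
  if (targetF > 0) {
    targetFs <- targetF / rateHz
    # the functional fraction is binding; burstDurationS sets the typical
    # burst and burstRate caps how many bursts a session can hold
    nBursts <- max(1L, min(round(profile$burstRate * minutes),
                           round(targetFs / profile$burstDurationS)))
    wts <- stats::rgamma(nBursts, shape = 4, rate = 4 / profile$burstDurationS)
    durF <- round(targetF * wts / sum(wts))
    durF[nBursts] <- targetF - sum(durF[-nBursts])
    durF <- pmax(durF, 1L)
    gapW <- stats::rgamma(nBursts + 1L, shape = 1)
    nNF <- nAct - sum(durF)
    gapN <- floor(nNF * gapW / sum(gapW))
    gapN[1] <- gapN[1] + (nNF - sum(gapN))
    pos <- actStart
    for (i in seq_len(nBursts)) {
      pos <- pos + gapN[i]
      len <- min(durF[i], n - pos + 1L)
      if (len > 0) {
        segs[[length(segs) + 1L]] <- c(pos, len)
        labels[pos:(pos + len - 1L)] <- "F"
      }
      pos <- pos + len
    }
  }

  # functional bursts: gravity tilt + low-frequency movement pulses
  for (sg in segs) {
    idx <- sg[1]:(sg[1] + sg[2] - 1L)
    tau <- seq(0, 1, length.out = length(idx))
    # onset/offset ramps bounded at 0.9 s so long bursts stay in motion for
    # almost their whole labeled extent
    durS <- length(idx) / rateHz
    r <- min(0.3, 0.9 / durS)
    env <- .smoothstep(tau / r) * .smoothstep((1 - tau) / r)
    theta <- stats::runif(1, profile$tiltRangeDeg[1],
                          profile$tiltRangeDeg[2]) * pi / 180 * env
    phi <- stats::runif(1, 0, 2 * pi)
    dirv <- numeric(3)
    dirv[oAx] <- c(cos(phi), sin(phi))
    g0 <- numeric(3); g0[gAx] <- 1
    a[idx, ] <- .tiltGravity(g0, dirv, theta)
    fm <- stats::runif(1, 0.8, 1.5)              # movement content ~1 Hz
    tb <- t[idx] - t[idx[1]]
    pulse <- 0.4 * sin(2 * pi * fm * tb + stats::runif(1, 0, 2 * pi)) * env
    a[idx, oAx[1]] <- a[idx, oAx[1]] + pulse
    a[idx, oAx[2]] <- a[idx, oAx[2]] +
      0.3 * sin(2 * pi * (fm * 1.7) * tb + stats::runif(1, 0, 2 * pi)) * env
  }

  # non-functional gaps alternate between rest and gait oscillation
  nfRuns <- rle(labels == "NF")
  ends <- cumsum(nfRuns$lengths)
  starts <- ends - nfRuns$lengths + 1L
  for (j in which(nfRuns$values)) {
    idx <- starts[j]:ends[j]
    idx <- idx[idx >= actStart]
    if (length(idx) < rateHz) next
    if (stats::runif(1) < 0.5 && profile$gaitAmplitudeG > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      a[idx, oAx[1]] <- a[idx, oAx[1]] +
        profile$gaitAmplitudeG * sin(2 * pi * 1.9 * t[idx] + ph)
      a[idx, gAx] <- a[idx, gAx] +
        0.3 * profile$gaitAmplitudeG * sin(2 * pi * 3.8 * t[idx] + 2 * ph)
    }
  }

  a <- a + matrix(stats::rnorm(3 * n, 0, profile$noiseSdG), n, 3)
  list(t = t, a = a, labels = labels)
}

#' Generate one synthetic session (both limbs)
#'
#' Simulates a recording session: a sync prelude of five z-axis oscillation
#' reversals, a short rest gap, then activity in which functional bursts
#' (smooth gravity re-orientation plus movement pulses) alternate with
#' non-functional stillness or gait oscillation. The empirical functional
#' fraction matches the profile's `functionalFraction` up to rounding.
#'
#' @param profile [movementProfile()] for the paretic limb.
#' @param rateHz sampling rate: 30, 50 or 200.
#' @param minutes session duration.
#' @param seed RNG seed.
#' @param pareticSide `"left"` or `"right"`.
#' @param nonpareticProfile profile for the non-paretic limb; defaults to the
#'   paretic profile.
#' @return A list with `traces` (named list of [RawTrace-class], by limb side)
#'   and `truth` (named list of ground-truth [LabelTrack-class] at the sensor
#'   rate, by limb side).
#' @export
generateSession <- function(profile, rateHz, minutes, seed,
                            pareticSide = "left", nonpareticProfile = NULL) {
  if (!rateHz %in% c(30, 50, 200))
    .stopf("unsupported sampling rate %s Hz: must be 30, 50 or 200", rateHz)
  stopifnot(inherits(profile, "MovementProfile"))
  if (is.null(nonpareticProfile)) nonpareticProfile <- profile
  nonSide <- setdiff(c("left", "right"), pareticSide)

  .withSeed(seed, {
    par <- .limbSession(profile, rateHz, minutes)
    non <- .limbSession(nonpareticProfile, rateHz, minutes)
    traces <- list()
    truth <- list()
    traces[[pareticSide]] <- rawTrace(par$t, par$a, rateHz, pareticSide,
                                      "paretic")
    traces[[nonSide]] <- rawTrace(non$t, non$a, rateHz, nonSide, "nonparetic")
    truth[[pareticSide]] <- labelTrack(par$labels, rateHz)
    truth[[nonSide]] <- labelTrack(non$labels, rateHz)
    list(traces = traces, truth = truth)
  })
}

#' Simulate annotator labels with disagreement near transitions
#'
#' Each annotator reproduces the ground-truth track except near label
#' transitions, where the perceived boundary shifts by up to
#' `transitionJitterS` and short unknown ("U") stretches may appear —
#' mimicking the fact that most human disagreement concerns the precise
#' timing of transitions. With zero jitter every annotator equals the truth.
#'
#' @param truth ground-truth [LabelTrack-class] on the video timeline.
#' @param annotators number of annotators (>= 1).
#' @param transitionJitterS disagreement half-width in seconds.
#' @param seed RNG seed.
#' @param limb limb name for the returned [AnnotationSet-class].
#' @return An [AnnotationSet-class] with one track per annotator.
#' @export
generateAnnotations <- function(truth, annotators = 3, transitionJitterS = 0.5,
                                seed = 1, limb = "left") {
  stopifnot(is(truth, "LabelTrack"))
  if (!.isCount(annotators) || annotators < 1)
    .stopf("annotators must be a count >= 1")
  lab <- labelValues(truth)
  rate <- sampleRate(truth)
  jn <- as.integer(round(transitionJitterS * rate))
  n <- length(lab)

  .withSeed(seed, {
    tracks <- lapply(seq_len(annotators), function(aIdx) {
      ann <- lab
      if (jn > 0) {
        bounds <- which(lab[-1] != lab[-n])       # boundary after index b
        for (b in bounds) {
          delta <- sample(seq(-jn, jn), 1)
          if (delta > 0) {
            to <- min(b + delta, n)
            ann[(b + 1):to] <- lab[b]
          } else if (delta < 0) {
            from <- max(b + delta + 1, 1)
            ann[from:b] <- lab[b + 1]
          }
          if (stats::runif(1) < 0.3) {
            uLen <- sample(seq_len(jn), 1)
            from <- max(b - floor(uLen / 2), max(b - jn + 1L, 1L))
            to <- min(from + uLen - 1L, min(b + jn, n))
            ann[from:to] <- "U"
          }
        }
      }
      stats::setNames(list(ann), limb)
    })
    annotationSet(tracks, rate)
  })
}

# Merge per-limb AnnotationSets (same annotators, same frame rate).
.mergeAnnotations <- function(a, b) {
  stopifnot(nAnnotators(a) == nAnnotators(b))
  tracks <- lapply(seq_len(nAnnotators(a)), function(i)
    c(a@tracks[[i]], b@tracks[[i]]))
  annotationSet(tracks, sampleRate(a))
}

#' Default paretic-side movement profiles for a cohort
#'
#' Paretic-limb functional fractions are drawn lower than the non-paretic
#' side (see [generateCohort()]), reflecting reduced real-world use of the
#' affected arm.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param noiseSdG sensor noise level passed to every profile.
#' @return List of `n` [movementProfile()] objects.
#' @export
defaultProfiles <- function(n, seed = 1, noiseSdG = 0.02) {
  .withSeed(seed, {
    lapply(seq_len(n), function(i)
      movementProfile(functionalFraction = stats::runif(1, 0.2, 0.5),
                      burstRate = stats::runif(1, 3, 5),
                      burstDurationS = stats::runif(1, 5, 7),
                      gaitAmplitudeG = stats::runif(1, 0.2, 0.3),
                      noiseSdG = noiseSdG))
  })
}

# Non-paretic profile derived from the paretic one: higher functional use.
.nonpareticFrom <- function(profile) {
  p <- profile
  p$functionalFraction <- min(0.6, 1.5 * p$functionalFraction + 0.1)
  p
}

#' Generate a synthetic cohort on disk
#'
#' Writes one accelerometer CSV per limb per subject, a per-subject
#' annotation CSV (video-frame labels from several annotators), and a YAML
#' manifest recording per-subject sampling rate, paretic side, empirical
#' functional fraction, the sensor/video clock relation and the video-side
#' sync peak times. Deterministic for a fixed seed.
#'
#' @param config a [cohortConfig()].
#' @param profiles list of paretic-limb [movementProfile()]s, one per subject.
#' @param outDir output directory (created if missing).
#' @param nonpareticProfiles optional list of non-paretic profiles; by default
#'   derived from the paretic ones with higher functional use.
#' @param subjectIds optional character ids; default `s01, s02, ...`.
#' @return Invisibly, the manifest path.
#' @export
generateCohort <- function(config, profiles, outDir,
                           nonpareticProfiles = NULL, subjectIds = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  if (length(profiles) == 0) .stopf("empty cohort: no profiles supplied")
  if (length(profiles) != config$nSubjects)
    .stopf("need %d profiles, got %d", config$nSubjects, length(profiles))
  if (is.null(subjectIds))
    subjectIds <- sprintf("s%02d", seq_len(config$nSubjects))
  if (anyDuplicated(subjectIds))
    .stopf("duplicate subject IDs: %s",
           paste(unique(subjectIds[duplicated(subjectIds)]), collapse = ", "))
  if (is.null(nonpareticProfiles))
    nonpareticProfiles <- lapply(profiles, .nonpareticFrom)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  frameRate <- 30
  manifest <- list(seed = config$seed, video_frame_rate_hz = frameRate,
                   session_minutes = config$sessionMinutes,
                   annotators = config$annotators, subjects = list())

  for (i in seq_len(config$nSubjects)) {
    sid <- subjectIds[i]
    seedI <- .childSeed(config$seed, i)
    pareticSide <- .withSeed(seedI + 1L, sample(c("left", "right"), 1))
    rate <- .withSeed(seedI + 2L, {
      rs <- config$ratesHz
      if (length(rs) == 1L) rs else sample(rs, 1)
    })
    clock <- .withSeed(seedI + 3L, list(
      offset_s = round(stats::runif(1, -1.5, -0.2), 6),
      scale = round(1 + stats::runif(1, -2e-4, 2e-4), 8)))

    ses <- generateSession(profiles[[i]], rate, config$sessionMinutes,
                           seed = seedI + 4L, pareticSide = pareticSide,
                           nonpareticProfile = nonpareticProfiles[[i]])

    # video timeline: starts before the sensor (offset < 0), covers it fully
    sesEnd <- max(timeStamps(ses$traces[[1]]))
    nFrames <- as.integer(floor((sesEnd - clock$offset_s) / clock$scale *
                                  frameRate))
    videoTruth <- lapply(ses$truth, function(tr)
      .truthOnVideoTimeline(tr, clock, frameRate, nFrames))

    annL <- generateAnnotations(videoTruth$left, config$annotators,
                                config$transitionJitterS, seed = seedI + 5L,
                                limb = "left")
    annR <- generateAnnotations(videoTruth$right, config$annotators,
                                config$transitionJitterS, seed = seedI + 6L,
                                limb = "right")
    ann <- .mergeAnnotations(annL, annR)

    files <- list(left = paste0(sid, "_left.csv"),
                  right = paste0(sid, "_right.csv"),
                  annotations = paste0(sid, "_annotations.csv"),
                  truth = paste0(sid, "_truth.csv"))
    writeAccelCsv(ses$traces$left, file.path(outDir, files$left))
    writeAccelCsv(ses$traces$right, file.path(outDir, files$right))
    writeAnnotationCsv(ann, file.path(outDir, files$annotations))
    .writeTruthCsv(ses$truth, file.path(outDir, files$truth))

    peakTimes <- .syncPeakTimes()
    fracPar <- mean(labelValues(ses$truth[[pareticSide]]) == "F")
    nonSide <- setdiff(c("left", "right"), pareticSide)
    fracNon <- mean(labelValues(ses$truth[[nonSide]]) == "F")
    manifest$subjects[[sid]] <- list(
      id = sid, rate_hz = rate, paretic_side = pareticSide,
      functional_fraction_paretic = round(fracPar, 4),
      functional_fraction_nonparetic = round(fracNon, 4),
      clock = clock,
      video_peaks_s = round((peakTimes - clock$offset_s) / clock$scale, 6),
      files = files)
  }

  manifestPath <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, manifestPath)
  invisible(manifestPath)
}

# Ground-truth labels resampled onto the video frame timeline. Frames before
# the sensor was attached are non-functional by construction.
.truthOnVideoTimeline <- function(truth, clock, frameRate, nFrames) {
  lab <- labelValues(truth)
  rate <- sampleRate(truth)
  tSensor <- clock$offset_s + clock$scale * (seq_len(nFrames) - 0.5) / frameRate
  idx <- round(tSensor * rate) + 1L
  out <- rep("NF", nFrames)
  ok <- idx >= 1L & idx <= length(lab)
  out[ok] <- lab[idx[ok]]
  labelTrack(out, frameRate)
}

.writeTruthCsv <- function(truth, path) {
  n <- nSamples(truth$left)
  data.table::fwrite(data.table::data.table(
    sample = seq_len(n) - 1L,
    left = labelValues(truth$left),
    right = labelValues(truth$right)), path)
}
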