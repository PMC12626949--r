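test_that("down-sampling to 30 Hz preserves counts and low-frequency content", {
  s <- generateSession(movementProfile(), 30, 1, seed = 1)
  expect_identical(resampleTo30Hz(s$traces$left), s$traces$left)

  # 200 Hz, 1 Hz sinusoid, 10 s -> 300 samples, amplitude within 1%
  t <- (0:1999) / 200
  a <- cbind(x = sin(2 * pi * t), y = 0 * t, z = 1 + 0 * t)
  tr <- rawTrace(t, a, 200, "right", "paretic")
  out <- resampleTo30Hz(tr)
  expect_equal(nSamples(out), 300L)
  tOut <- timeStamps(out)
  mid <- tOut > 1 & tOut < 9                # away from filter edge effects
  expect_lt(max(abs(accelMatrix(out)[mid, "x"] - sin(2 * pi * tOut[mid]))),
            0.01)

  # 50 Hz, 10 s (500 samples) -> 300 samples
  t50 <- (0:499) / 50
  tr50 <- rawTrace(t50, cbind(x = 0 * t50, y = 0 * t50, z = 1 + 0 * t50),
                   50, "left", "nonparetic")
  expect_equal(nSamples(resampleTo30Hz(tr50)), 300L)

  tr20 <- rawTrace((0:99) / 20, matrix(1, 100, 3), 20, "left", "paretic")
  expect_error(resampleTo30Hz(tr20), "unsupported rate")
})

test_that("axis harmonization mirrors left traces and is an involution", {
  t <- (0:9) / 30
  a <- cbind(x = 1:10, y = 11:20, z = 21:30)
  right <- rawTrace(t, a, 30, "right", "paretic")
  expect_identical(harmonizeAxes(right), right)

  left <- rawTrace(t, a, 30, "left", "paretic")
  h <- harmonizeAxes(left)
  expect_equal(accelMatrix(h)[, "x"], -a[, "x"], ignore_attr = TRUE)
  expect_equal(accelMatrix(h)[, "y"], a[, "y"], ignore_attr = TRUE)
  expect_equal(accelMatrix(harmonizeAxes(h)), accelMatrix(left))
})

test_that("consensus voting matches the brute-force mode oracle", {
  mk <- function(...) annotationSet(lapply(list(...), function(v)
    list(left = v)), 30)
  expect_identical(labelValues(consensusLabels(mk(c("F"), c("F"), c("NF")),
                                               "left")), "F")
  expect_identical(labelValues(consensusLabels(mk(c("F"), c("NF"), c("U")),
                                               "left")), "U")

  set.seed(42)
  for (rep in 1:5) {
    tracks <- lapply(1:3, function(i)
      sample(c("F", "NF", "U"), 1000, replace = TRUE))
    ann <- annotationSet(lapply(tracks, function(v) list(left = v)), 30)
    expect_identical(labelValues(consensusLabels(ann, "left")),
                     oracleConsensus(tracks))
  }
})

test_that("pairwise annotator agreement matches brute force", {
  mk <- function(...) annotationSet(lapply(list(...), function(v)
    list(left = v)), 30)
  same <- c("F", "F", "NF", "U")
  expect_equal(annotatorAgreement(mk(same, same), "left"), 100)
  expect_equal(annotatorAgreement(mk(same, c("F", "NF", "NF", "U")), "left"),
               75)
  expect_error(annotatorAgreement(mk(same), "left"), ">= 2")

  set.seed(3)
  tracks <- lapply(1:4, function(i) sample(c("F", "NF", "U"), 200, TRUE))
  ann <- annotationSet(lapply(tracks, function(v) list(left = v)), 30)
  expect_equal(annotatorAgreement(ann, "left"), oracleAgreement(tracks))
})

test_that("label transfer maps video frames onto the sensor timeline", {
  lab <- sample(c("F", "NF"), 90, replace = TRUE)
  track <- labelTrack(lab, 30)
  idMap <- clockMap(0, 1)
  expect_identical(labelValues(transferLabels(track, idMap, 90)), lab)

  # 15 Hz frames: each frame label repeated twice at 30 Hz
  tr15 <- labelTrack(lab[1:30], 15)
  out <- transferLabels(tr15, idMap, 60)
  expect_identical(labelValues(out), rep(lab[1:30], each = 2))

  # +1 s sensor offset shifts labels by 30 samples; brute-force lookup oracle
  offMap <- clockMap(1, 1)
  got <- labelValues(transferLabels(track, offMap, 90))
  expected <- vapply(seq_len(90), function(i) {
    v <- ((i - 1) / 30 - 1)                      # mapped video time
    frame <- NA_integer_                         # interval search per frame
    for (j in seq_len(90))
      if (v >= (j - 1) / 30 - 1e-8 && v < j / 30 - 1e-8) { frame <- j; break }
    if (!is.na(frame)) lab[frame] else "U"
  }, "")
  expect_identical(got, expected)
  expect_identical(got[31:90], lab[1:60])
})

test_that("windowing tiles contiguous runs and drops ties, matching oracle", {
  mkTrace <- function(n) rawTrace((seq_len(n) - 1) / 30,
                                  matrix(rnorm(3 * n), n, 3), 30, "right",
                                  "paretic")
  ds <- segmentAndWindow(mkTrace(150), labelTrack(rep("NF", 150), 30))
  expect_equal(nSamples(ds), 2L)
  expect_true(all(windowLabels(ds) == 0L))

  ds59 <- segmentAndWindow(mkTrace(59), labelTrack(rep("NF", 59), 30))
  expect_equal(nSamples(ds59), 0L)

  lab <- c(rep("F", 70), rep("U", 10), rep("NF", 130))
  ds3 <- segmentAndWindow(mkTrace(210), labelTrack(lab, 30))
  expect_equal(sum(windowLabels(ds3) == 1L), 1L)
  expect_equal(sum(windowLabels(ds3) == 0L), 2L)

  for (s in 1:30) {
    lab <- randomLabelRuns(nRuns = sample(3:12, 1), seed = s)
    n <- length(lab)
    ds <- segmentAndWindow(mkTrace(n), labelTrack(lab, 30))
    want <- oracleTile(lab, 60)
    expect_equal(nSamples(ds), length(want))
    if (length(want))
      expect_identical(windowLabels(ds), as.integer(want == "F"))
  }
})

test_that("combined variant uses paretic labels and loses windows to either arm's unknowns", {
  n <- 600
  mk <- function() rawTrace((seq_len(n) - 1) / 30, matrix(rnorm(3 * n), n, 3),
                            30, "right", "paretic")
  labP <- labelTrack(rep(c("F", "NF"), each = n / 2), 30)
  labN <- labelTrack(rep("NF", n), 30)
  par <- list(trace = mk(), labels = labP)
  non <- list(trace = mk(), labels = labN)

  dsP <- assembleVariant(par, non, "paretic")
  dsC <- assembleVariant(par, non, "combined")
  expect_equal(nSamples(dsC), nSamples(dsP))     # no unknowns anywhere
  expect_equal(dim(windowArray(dsC))[3], 6L)
  expect_identical(windowLabels(dsC), windowLabels(dsP))

  labN2 <- rep("NF", n)
  labN2[200:260] <- "U"
  dsC2 <- assembleVariant(par, list(trace = non$trace,
                                    labels = labelTrack(labN2, 30)),
                          "combined")
  expect_lt(nSamples(dsC2), nSamples(dsP))

  bad <- list(trace = rawTrace((1:10) / 30, matrix(0, 10, 3), 30, "right",
                               "nonparetic"),
              labels = labelTrack(rep("NF", 10), 30))
  expect_error(assembleVariant(par, bad, "combined"), "timeline mismatch")
})

test_that("robust scaler normalizes the fit set and matches quantile oracle", {
  set.seed(8)
  x <- array(rnorm(40 * 60 * 3, mean = 2, sd = 3), c(40, 60, 3))
  sc <- fitScaler(x)
  for (ch in 1:3) {
    v <- as.vector(x[, , ch])
    expect_equal(sc$median[ch], oracleQuantile(v, 0.5))
    expect_equal(sc$iqr[ch],
                 oracleQuantile(v, 0.75) - oracleQuantile(v, 0.25))
  }
  xs <- applyScaler(sc, x)
  for (ch in 1:3) {
    v <- as.vector(xs[, , ch])
    expect_lt(abs(median(v)), 1e-9)
    expect_lt(abs((quantile(v, 0.75) - quantile(v, 0.25)) - 1), 1e-9)
  }

  # identity for a channel already at median 0 / IQR 1
  xi <- array(c(rep(c(-0.5, 0, 0.5, 1, -1), 24 * 3)), c(2, 60, 3))
  sci <- fitScaler(xi)
  expect_equal(applyScaler(sci, xi), xi, tolerance = 1e-12)

  # constant channel: warning, output all zeros
  xc <- x
  xc[, , 2] <- 5
  expect_warning(scc <- fitScaler(xc), "constant")
  xcs <- applyScaler(scc, xc)
  expect_true(all(xcs[, , 2] == 0))

  expect_error(fitScaler(array(0, c(0, 60, 3))), "empty")

  # affine per channel: scaling commutes predictably
  a <- applyScaler(sc, 2 * x)
  b <- (2 * x - array(rep(sc$median, each = 40 * 60), dim(x))) /
    array(rep(sc$iqr, each = 40 * 60), dim(x))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("unknown labels never reach a windowed dataset", {
  for (s in 1:10) {
    lab <- randomLabelRuns(nRuns = 8, seed = 100 + s)
    n <- length(lab)
    tr <- rawTrace((seq_len(n) - 1) / 30, matrix(rnorm(3 * n), n, 3), 30,
                   "right", "paretic")
    ds <- segmentAndWindow(tr, labelTrack(lab, 30))
    expect_true(all(windowLabels(ds) %in% c(0L, 1L)))
  }
})
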