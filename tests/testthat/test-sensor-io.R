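test_that("accelerometer CSV round trip and schema errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z",
               "0.000,0.01,0.02,1.00",
               "0.033,0.02,0.01,0.99",
               "0.067,0.00,0.03,1.01",
               "0.100,0.01,0.02,1.00"), f)
  tr <- readAccelCsv(f, "left", "paretic")
  expect_s4_class(tr, "RawTrace")
  expect_equal(nSamples(tr), 4L)
  expect_equal(sampleRate(tr), 30)

  # write-then-read reproduces a generated trace within float formatting
  s <- generateSession(movementProfile(), 30, 1, seed = 1)
  g <- tempfile(fileext = ".csv")
  writeAccelCsv(s$traces$left, g)
  back <- readAccelCsv(g, "left", "paretic")
  expect_equal(accelMatrix(back), accelMatrix(s$traces$left),
               tolerance = 1e-12)

  writeLines(c("timestamp,x,y,z", "0.1,0,0,1", "0.0,0,0,1"), f)
  expect_error(readAccelCsv(f, "left", "paretic"), "monoton|increasing")
  writeLines(c("timestamp,x,y", "0,0,0"), f)
  expect_error(readAccelCsv(f, "left", "paretic"), "missing column")
})

test_that("sync peaks: five reversals found, wrong counts are errors", {
  s <- generateSession(movementProfile(), 30, 1, seed = 6)
  peaks <- detectSyncPeaks(s$traces$left)
  expect_length(peaks, 5)
  expect_true(all(diff(peaks) > 0))
  expect_true(all(abs(diff(peaks) - 0.25) < 0.05))

  # gravity offset invariance: adding a constant to z changes nothing
  a2 <- accelMatrix(s$traces$left)
  a2[, "z"] <- a2[, "z"] + 0.7
  tr2 <- rawTrace(timeStamps(s$traces$left), a2, 30, "left", "paretic")
  expect_equal(detectSyncPeaks(tr2), peaks)

  # flat trace -> sync failure reporting 0 peaks
  flat <- rawTrace((0:299) / 30, matrix(0, 300, 3), 30, "left", "paretic")
  expect_error(detectSyncPeaks(flat), "found 0")

  # a 4-oscillation prelude cannot satisfy expected = 5
  t <- (0:299) / 30
  z <- ifelse(t <= 1.0, 2 * sin(2 * pi * 2 * t), 0)
  tr4 <- rawTrace(t, cbind(x = 0 * t, y = 0 * t, z = z + 1), 30, "left",
                  "paretic")
  expect_error(detectSyncPeaks(tr4), "found 4")
})

test_that("clock alignment recovers offset and drift", {
  a <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  id <- alignClocks(a, a)
  expect_equal(id$offsetS, 0)
  expect_equal(id$scale, 1)

  sh <- alignClocks(a, a - 3.0)
  expect_equal(sh$offsetS, 3.0)
  expect_equal(sh$scale, 1)

  v <- (a - 0.8) / 1.001                    # sensor = 0.8 + 1.001 * video
  fit <- alignClocks(a, v)
  expect_lt(abs(fit$scale - 1.001), 1e-6)
  expect_lt(abs(fit$offsetS - 0.8), 1e-6)
  expect_lt(fit$residualRmsS, 1e-9)

  expect_error(alignClocks(1, 1), "at least 2")
  expect_error(alignClocks(a, a[-1]), "length")

  # identity property on random valid peak lists
  for (s in 1:20) {
    set.seed(s)
    pk <- sort(runif(5, 0, 3))
    m <- alignClocks(pk, pk)
    expect_equal(m$offsetS, 0, tolerance = 1e-10)
    expect_equal(m$scale, 1, tolerance = 1e-10)
  }
})
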