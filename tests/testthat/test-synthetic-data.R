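test_that("session length, functional fraction and degenerate fraction", {
  # zero functional use -> no functional labels anywhere
  p0 <- movementProfile(functionalFraction = 0)
  s0 <- generateSession(p0, 30, 2, seed = 1)
  expect_false(any(labelValues(s0$truth$left) == "F"))

  # 200 Hz x 1 min -> 12000 samples
  s200 <- generateSession(p0, 200, 1, seed = 1)
  expect_equal(nSamples(s200$traces$left), 12000L)

  # empirical functional fraction tracks the profile
  p4 <- movementProfile(functionalFraction = 0.4)
  s4 <- generateSession(p4, 30, 10, seed = 1)
  frac <- mean(labelValues(s4$truth$left) == "F")
  expect_gte(frac, 0.35)
  expect_lte(frac, 0.45)

  expect_error(generateSession(p0, 25, 1, seed = 1), "unsupported")
})

test_that("sessions are bit-reproducible for a fixed seed", {
  p <- movementProfile(functionalFraction = 0.3)
  a <- generateSession(p, 50, 2, seed = 9)
  b <- generateSession(p, 50, 2, seed = 9)
  expect_identical(accelMatrix(a$traces$left), accelMatrix(b$traces$left))
  expect_identical(labelValues(a$truth$right), labelValues(b$truth$right))
})

test_that("resting samples carry one gravity on the configured axis", {
  p <- movementProfile(functionalFraction = 0, gaitAmplitudeG = 0,
                       noiseSdG = 0.02, gravityAxis = "y")
  s <- generateSession(p, 30, 2, seed = 3)
  a <- accelMatrix(s$traces$left)
  rest <- a[-(1:90), ]                       # skip prelude + gap
  mag <- sqrt(rowSums(rest^2))
  expect_lt(abs(mean(mag) - 1), 0.02 + 0.01)
  expect_gt(mean(rest[, 2]), 0.95)           # +1 g on y
})

test_that("a moving-std threshold separates rest from functional movement", {
  p <- movementProfile(functionalFraction = 0.4, gaitAmplitudeG = 0,
                       noiseSdG = 0.02)
  s <- generateSession(p, 30, 10, seed = 5)
  a <- accelMatrix(s$traces$left)
  lab <- labelValues(s$truth$left)
  mag <- sqrt(rowSums(a^2))
  w <- 15
  rollSd <- vapply(seq(w + 1, length(mag) - w), function(i)
    sd(mag[(i - w):(i + w)]), 1)
  labMid <- lab[seq(w + 1, length(mag) - w)]
  # skip the prelude and a small boundary margin around transitions
  inner <- seq_along(labMid) > 90
  bnd <- which(labMid[-1] != labMid[-length(labMid)])
  near <- unique(unlist(lapply(bnd, function(b)
    max(1, b - w):min(length(labMid), b + w))))
  use <- setdiff(which(inner), near)
  pred <- ifelse(rollSd[use] > 0.05, "F", "NF")
  expect_gte(mean(pred == labMid[use]), 0.99)
})

test_that("annotator jitter is confined to transition neighborhoods", {
  p <- movementProfile(functionalFraction = 0.3)
  s <- generateSession(p, 30, 5, seed = 2)
  truth <- s$truth$left
  lab <- labelValues(truth)

  # zero jitter -> all annotators equal truth, agreement 100%, consensus = truth
  ann0 <- generateAnnotations(truth, annotators = 3, transitionJitterS = 0,
                              seed = 1)
  for (tr in annotatorTracks(ann0, "left")) expect_identical(tr, lab)
  expect_equal(annotatorAgreement(ann0, "left"), 100)
  expect_identical(labelValues(consensusLabels(ann0, "left")), lab)

  # 0.5 s jitter at 30 Hz -> all disagreements within 15 samples of a boundary
  ann <- generateAnnotations(truth, annotators = 3, transitionJitterS = 0.5,
                             seed = 4)
  bounds <- which(lab[-1] != lab[-length(lab)])
  for (tr in annotatorTracks(ann, "left")) {
    bad <- which(tr != lab)
    if (length(bad)) {
      dist <- vapply(bad, function(i) min(abs(i - bounds), abs(i - bounds - 1)),
                     1)
      expect_lte(max(dist), 15)
    }
  }
})

test_that("cohorts are deterministic and manifest fractions match profiles", {
  profs <- lapply(c(0.03, 0.3, 0.5), function(ff)
    movementProfile(functionalFraction = ff))
  cfg <- cohortConfig(3, ratesHz = 30, sessionMinutes = 4, seed = 7)
  d1 <- tempfile("coh1")
  d2 <- tempfile("coh2")
  generateCohort(cfg, profs, d1)
  generateCohort(cfg, profs, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.yaml"))),
                   unname(tools::md5sum(file.path(d2, "manifest.yaml"))))

  man <- readManifest(d1)
  got <- vapply(man$subjects, function(e) e$functional_fraction_paretic, 1)
  expect_true(all(abs(got - c(0.03, 0.3, 0.5)) <= 0.05))

  expect_error(generateCohort(cfg, profs, d1, subjectIds = c("a", "a", "b")),
               "duplicate")
  expect_error(cohortConfig(0), "nSubjects")
  expect_error(generateCohort(cfg, list(), d1), "empty|profiles")
})
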