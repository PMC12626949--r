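test_that("SMOTE interpolation geometry", {
  # identical minority points -> identical synthetics
  x <- array(rep(c(1, 2, 3), each = 10), c(10, 3, 3))[, , , drop = FALSE]
  x <- array(1.5, c(8, 60, 3))
  s <- smoteSynthesize(x, 20, k = 3, seed = 1)
  expect_true(all(s == 1.5))

  # two points, k = 1 -> every synthetic lies on the segment [a, b]
  ab <- array(0, c(2, 60, 3))
  ab[2, , ] <- 1
  s2 <- smoteSynthesize(ab, 50, k = 1, seed = 2)
  flat <- matrix(s2, 50, 180)
  expect_true(all(apply(flat, 1, function(r) diff(range(r)) < 1e-12)))
  expect_true(all(flat >= 0 & flat <= 1))

  expect_error(smoteSynthesize(ab, 5, k = 5), "more minority")
})

test_that("synthetics interpolate recorded parent/neighbor pairs; kNN matches brute force", {
  set.seed(4)
  x <- array(rnorm(50 * 60 * 3), c(50, 60, 3))
  s <- smoteSynthesize(x, 100, k = 5, seed = 9)
  prov <- attr(s, "provenance")
  expect_equal(nrow(prov), 100)
  flat <- matrix(x, 50, 180)
  sflat <- matrix(s, 100, 180)
  for (i in seq_len(100)) {
    a <- flat[prov$parent[i], ]
    b <- flat[prov$neighbor[i], ]
    expect_lt(max(abs(sflat[i, ] - (a + prov$u[i] * (b - a)))), 1e-9)
  }
  # the recorded neighbors really are among the k nearest (brute force)
  knn <- oracleKnn(flat, 5)
  for (i in seq_len(100))
    expect_true(prov$neighbor[i] %in% knn[prov$parent[i], ])
})

test_that("rebalancing hits the exact target ratio law", {
  mk <- function(nMin, nMaj) {
    set.seed(nMin + nMaj)
    x <- array(rnorm((nMin + nMaj) * 60 * 3), c(nMin + nMaj, 60, 3))
    y <- c(rep(1L, nMin), rep(0L, nMaj))
    list(x = x, y = y)
  }
  d <- mk(58, 942)
  r <- rebalanceTrainingSet(d$x, d$y, config = smoteConfig(0.5, seed = 1))
  expect_equal(sum(r$y == 1L), 471L)
  expect_equal(mean(r$y == 1L) * 100, 33.3, tolerance = 0.01)

  d2 <- mk(30, 100)
  r2 <- rebalanceTrainingSet(d2$x, d2$y, config = smoteConfig(0.5, seed = 1))
  expect_equal(r2$nSynthetic, 20L)

  # already at or above the target ratio -> untouched
  d3 <- mk(50, 50)
  r3 <- rebalanceTrainingSet(d3$x, d3$y, config = smoteConfig(0.5))
  expect_identical(r3$x, d3$x)
  expect_equal(r3$nSynthetic, 0L)

  expect_error(rebalanceTrainingSet(d$x, rep(0L, 1000),
                                    config = smoteConfig(0.5)),
               "single-class")
})

test_that("synthetics stay within the minority bounding box and keep provenance tags", {
  set.seed(5)
  x <- array(rnorm(30 * 60 * 3), c(30, 60, 3))
  y <- c(rep(1L, 12), rep(0L, 18))
  sid <- sprintf("s%02d", rep(1:3, each = 10))
  r <- rebalanceTrainingSet(x, y, sid, smoteConfig(1.0, kNeighbors = 3,
                                                   seed = 3))
  expect_equal(sum(r$y == 1L), 18L)
  synth <- r$x[r$synthetic, , , drop = FALSE]
  minW <- x[y == 1L, , , drop = FALSE]
  expect_true(all(synth >= min(minW) - 1e-9 & synth <= max(minW) + 1e-9))
  expect_length(r$subjectIds, dim(r$x)[1])
  expect_true(all(r$subjectIds[r$synthetic] %in% sid[y == 1L]))
})
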