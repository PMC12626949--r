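test_that("architecture spec has the fixed block structure", {
  spec <- buildArchitecture(c(60, 3, 1))
  expect_length(spec$convBlocks, 2)
  expect_length(spec$denseBlocks, 2)
  expect_equal(vapply(spec$convBlocks, `[[`, 1L, "filters"), c(16L, 32L))
  expect_equal(vapply(spec$convBlocks, function(b) b$dropout, 1),
               c(0.2, 0.2))
  expect_equal(vapply(spec$denseBlocks, `[[`, 1L, "units"), c(64L, 64L))
  expect_equal(vapply(spec$denseBlocks, function(b) b$l2, 1), c(1e-3, 1e-3))
  expect_equal(vapply(spec$denseBlocks, function(b) b$dropout, 1),
               c(0.3, 0.3))
  expect_equal(spec$head$activation, "sigmoid")
  expect_equal(spec$padding, "same")

  spec6 <- buildArchitecture(c(60, 6, 1))
  expect_equal(spec6$inputShape[2], 6L)
  expect_error(buildArchitecture(c(60, 4, 1)), "channel")
  expect_error(buildArchitecture(c(50, 3, 1)), "window length")
})

test_that("analytic parameter count matches the built weight tensors", {
  # hand-checked pieces: dense 64 -> 1 head contributes 65; first conv 160
  spec <- buildArchitecture(c(60, 3, 1))
  expect_equal(3 * 3 * 1 * 16 + 16, 160)
  expect_equal(64 * 1 + 1, 65)
  expect_equal(as.integer(countParameters(spec)), oracleWeightCount(spec))
  expect_equal(attr(countParameters(spec), "nonTrainable"), 96L)

  spec6 <- buildArchitecture(c(60, 6, 1))
  expect_equal(as.integer(countParameters(spec6)), oracleWeightCount(spec6))

  # formula holds across randomized layer widths
  set.seed(1)
  for (i in 1:100) {
    sp <- spec
    sp$convBlocks[[1]]$filters <- sample(4:32, 1)
    sp$convBlocks[[2]]$filters <- sample(4:48, 1)
    sp$denseBlocks[[1]]$units <- sample(8:96, 1)
    sp$denseBlocks[[2]]$units <- sample(8:96, 1)
    sp$inputShape[2] <- sample(c(3L, 6L), 1)
    f1 <- sp$convBlocks[[1]]$filters; f2 <- sp$convBlocks[[2]]$filters
    u1 <- sp$denseBlocks[[1]]$units; u2 <- sp$denseBlocks[[2]]$units
    analytic <- (9 * f1 + f1) + (9 * f1 * f2 + f2) + 2 * f1 + 2 * f2 +
      (60 * sp$inputShape[2] * f2 * u1 + u1) + (u1 * u2 + u2) + (u2 + 1)
    expect_equal(oracleWeightCount(sp), analytic)
  }
})

test_that("training fits separable data and refuses single-class input", {
  d <- separableWindows(90, 90, seed = 5)
  v <- separableWindows(30, 30, seed = 6)
  m <- trainModel(d$x, d$y, v$x, v$y, fastTrainConfig(maxEpochs = 60))
  h <- trainingHistory(m)
  expect_gte(max(h$accuracy), 0.99)
  expect_lte(m@epochsRun, 700L)

  # held-out prediction quality on the generator-guaranteed margin
  p <- predictProba(m, v$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean(classifyProb(p) == v$y), 0.95)

  expect_error(trainModel(d$x, rep(1L, 180), v$x, v$y, fastTrainConfig()),
               "single class|rebalance")
})

test_that("constant-input data converge to the majority rate", {
  x <- array(0.5, c(120, 60, 3))
  y <- rep(c(0L, 1L), times = c(84, 36))          # 70% majority class
  vx <- array(0.5, c(40, 60, 3))
  vy <- rep(c(0L, 1L), times = c(28, 12))
  m <- trainModel(x, y, vx, vy, fastTrainConfig(maxEpochs = 30))
  p <- predictProba(m, vx)
  acc <- mean(classifyProb(p) == vy)
  expect_equal(acc, 0.7, tolerance = 0.01)
})

test_that("training is deterministic for a fixed seed", {
  d <- separableWindows(40, 40, seed = 7)
  v <- separableWindows(10, 10, seed = 8)
  cfg <- fastTrainConfig(maxEpochs = 8, seed = 123)
  m1 <- trainModel(d$x, d$y, v$x, v$y, cfg)
  m2 <- trainModel(d$x, d$y, v$x, v$y, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@weights, m2@weights)
})

test_that("early stopping restores the best-validation-epoch weights", {
  d <- separableWindows(60, 60, seed = 9, noise = 0.6)
  v <- separableWindows(25, 25, seed = 10, noise = 0.6)
  m <- trainModel(d$x, d$y, v$x, v$y, fastTrainConfig(maxEpochs = 40,
                                                      seed = 2))
  h <- trainingHistory(m)
  accNow <- mean(classifyProb(predictProba(m, v$x)) == v$y)
  expect_equal(accNow, max(h$val_accuracy))
})

test_that("inference is deterministic (dropout and batch stats frozen)", {
  d <- separableWindows(30, 30, seed = 11)
  m <- trainModel(d$x, d$y, d$x, d$y, fastTrainConfig(maxEpochs = 5))
  expect_identical(predictProba(m, d$x), predictProba(m, d$x))
})

test_that("classification threshold rule", {
  expect_identical(classifyProb(c(0.2, 0.5, 0.9)), c(0L, 1L, 1L))
  expect_identical(classifyProb(c(0.2, 0.5, 0.9), threshold = 0),
                   c(1L, 1L, 1L))
  expect_error(classifyProb(c(-0.1, 0.5)), "\\[0, 1\\]")
  d <- separableWindows(10, 10, seed = 1)
  m <- trainModel(d$x, d$y, d$x, d$y, fastTrainConfig(maxEpochs = 3))
  expect_error(predictProba(m, array(0, c(5, 60, 6))), "shape|match")
})

test_that("dropping the L2 penalty does not hurt training-set fit", {
  accFor <- function(l2, seed) {
    d <- separableWindows(50, 50, seed = 20)
    spec <- buildArchitecture(c(60, 3, 1))
    spec$denseBlocks[[1]]$l2 <- l2
    spec$denseBlocks[[2]]$l2 <- l2
    cfg <- fastTrainConfig(maxEpochs = 25, seed = seed)
    set.seed(seed)
    w <- armetry:::.initWeights(spec)
    st <- armetry:::.adamInit(w)
    Xf <- armetry:::.flattenWindows(d$x)
    acc <- 0
    for (e in 1:25) {
      r <- armetry:::.nnEpoch(w, st, 1e-3, Xf, d$y, 60L, 3L,
                              sample.int(100), cfg, spec)
      w <- r$w; st <- r$adam
      acc <- r$accSum / 100
    }
    acc
  }
  for (s in 1:2) expect_gte(accFor(0, s) + 1e-9, accFor(1e-3, s))
})
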