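test_that("k-fold plans partition the windows with near-equal sizes", {
  plan <- makeIntrasubjectFolds(100, k = 5, seed = 1)
  sizes <- vapply(plan$folds, function(f) length(f$test), 1L)
  expect_true(all(sizes == 20))
  allTest <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(allTest, 1:100)
  for (f in plan$folds) expect_length(intersect(f$train, f$test), 0)

  # stratified: 10 minority windows over 5 folds -> 2 each
  y <- c(rep(0L, 90), rep(1L, 10))
  sp <- makeIntrasubjectFolds(y, k = 5, seed = 2)
  minCounts <- vapply(sp$folds, function(f) sum(y[f$test] == 1L), 1L)
  expect_true(all(minCounts %in% 1:3))
  expect_equal(sum(minCounts), 10L)
  sizes <- vapply(sp$folds, function(f) length(f$test), 1L)
  expect_lte(diff(range(sizes)), 1)

  expect_error(makeIntrasubjectFolds(3, k = 5), "cannot make")
})

test_that("LOSO plans test each subject exactly once with no leakage", {
  sid <- rep(c("a", "b", "c"), times = c(10, 20, 30))
  plan <- makeLosoFolds(sid)
  expect_length(plan$folds, 3)
  expect_equal(vapply(plan$folds, function(f) length(f$test), 1L),
               c(10L, 20L, 30L))
  for (f in plan$folds)
    expect_length(intersect(unique(sid[f$train]), unique(sid[f$test])), 0)
  expect_error(makeLosoFolds(rep("a", 5)), ">= 2 subjects")
})

test_that("metrics match hand counts and the brute-force tally", {
  perfect <- computeMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1Functional, 1)
  expect_equal(perfect$f1Nonfunctional, 1)

  inverted <- computeMetrics(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$f1Functional, 0)
  expect_equal(inverted$f1Nonfunctional, 0)

  m <- computeMetrics(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1))
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$f1Functional, 0.5)
  expect_equal(m$f1Nonfunctional, 2 / 3)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(1, 1, 2, 1))

  expect_warning(z <- computeMetrics(c(0, 0), c(0, 0)), "absent")
  expect_equal(z$f1Functional, 0)

  expect_error(computeMetrics(c(1, 0), c(1, 0, 0)), "length mismatch")

  set.seed(6)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    yt <- rbinom(n, 1, 0.5)
    yp <- rbinom(n, 1, 0.5)
    got <- suppressWarnings(computeMetrics(yt, yp))
    want <- oracleMetrics(yt, yp)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$f1Functional, want$f1Functional)
    expect_equal(got$f1Nonfunctional, want$f1Nonfunctional)
  }
})

test_that("aggregation: closed forms, nesting, permutation invariance", {
  df1 <- data.frame(subject = "s1", fold = 1, accuracy = 0.9,
                    f1Functional = 0.8, f1Nonfunctional = 0.85)
  expect_warning(a1 <- aggregateMetrics(df1, level = "fold"), "single")
  expect_equal(a1$mean[a1$metric == "accuracy"], 0.9)
  expect_equal(a1$sd[a1$metric == "accuracy"], 0)

  df2 <- data.frame(subject = c("s1", "s2"), fold = 1,
                    accuracy = c(0.8, 0.9), f1Functional = c(0.8, 0.9),
                    f1Nonfunctional = c(0.8, 0.9))
  a2 <- aggregateMetrics(df2, level = "fold")
  expect_equal(a2$mean[1], 0.85)
  expect_equal(a2$sd[1], 0.0707, tolerance = 1e-3)

  # two-stage (fold -> subject) equals the brute-force nested mean
  set.seed(7)
  df3 <- data.frame(subject = rep(c("s1", "s2", "s3"), each = 5),
                    fold = rep(1:5, 3),
                    accuracy = runif(15), f1Functional = runif(15),
                    f1Nonfunctional = runif(15))
  a3 <- aggregateMetrics(df3, level = "subject")
  perSub <- vapply(c("s1", "s2", "s3"), function(s)
    mean(df3$accuracy[df3$subject == s]), 1)
  expect_equal(a3$mean[a3$metric == "accuracy"], mean(perSub))
  expect_equal(a3$sd[a3$metric == "accuracy"], sd(perSub))

  shuf <- df3[sample(nrow(df3)), ]
  expect_equal(aggregateMetrics(shuf, level = "subject")$mean, a3$mean)

  expect_error(aggregateMetrics(df3[0, ], level = "fold"), "nothing")
})

test_that("paired comparison matches the step-by-step formula oracle", {
  tr <- c(0.9, 0.85, 0.95, 0.9)
  same <- pairedComparison(tr, tr)
  expect_equal(same$cohensD, 0)
  expect_true(same$ci95[1] <= 0 && same$ci95[2] >= 0)

  # constant shift: zero-variance differences -> p and dz undefined
  shift <- pairedComparison(tr, tr - 0.05)
  expect_true(is.na(shift$pValue))
  expect_true(is.na(shift$dz))
  expect_gt(shift$cohensD, 0)

  set.seed(34)
  n <- 34
  train <- rnorm(n, 0.9, 0.06)
  val <- train - rnorm(n, 0.05, 0.03)
  got <- pairedComparison(train, val)

  d <- train - val
  sdP <- sqrt((sd(train)^2 + sd(val)^2) / 2)
  dWant <- mean(d) / sdP
  r <- cor(train, val)
  se <- sqrt(1 / n + dWant^2 / (2 * n)) * sqrt(2 * (1 - r))
  tStat <- mean(d) / (sd(d) / sqrt(n))
  pWant <- 2 * pt(-abs(tStat), n - 1)
  expect_equal(got$cohensD, dWant)
  expect_equal(got$pValue, pWant)
  expect_equal(got$ci95, dWant + c(-1.96, 1.96) * se)
  expect_equal(got$dz, mean(d) / sd(d))

  expect_error(pairedComparison(1:3, 1:2), "length")
  expect_error(pairedComparison(1, 1), "n >= 2")
})
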