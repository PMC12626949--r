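# Programmatic fixtures shared across test files.

# Directly constructed two-class window set with a large margin: class 0 is
# gravity-on-z noise, class 1 adds a mean shift and a slow oscillation on x.
separableWindows <- function(n0, n1, seed = 1, C = 3, noise = 0.1) {
  set.seed(seed)
  n <- n0 + n1
  X <- array(rnorm(n * 60 * C, 0, noise), c(n, 60, C))
  X[, , min(3, C)] <- X[, , min(3, C)] + 1
  if (n1 > 0) {
    idx <- (n0 + 1):n
    X[idx, , 1] <- X[idx, , 1] + 0.8 +
      0.4 * sin(outer(rep(1, length(idx)), 2 * pi * (1:60) / 60))
    X[idx, , min(3, C)] <- X[idx, , min(3, C)] - 0.5
  }
  list(x = X, y = c(rep(0L, n0), rep(1L, n1)))
}

# Random F/NF/U label vector with controllable run structure.
randomLabelRuns <- function(nRuns, seed, maxLen = 150) {
  set.seed(seed)
  labs <- sample(c("F", "NF", "U"), nRuns, replace = TRUE)
  unlist(lapply(labs, function(l) rep(l, sample.int(maxLen, 1))))
}

# A cached tiny cohort for pipeline-level tests.
tinyCohortDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.yaml"))) {
      dir <<- file.path(tempdir(), "armetry-tiny-cohort")
      if (!file.exists(file.path(dir, "manifest.yaml")))
        simulateCohort(dir, nSubjects = 3, seed = 11, sessionMinutes = 3)
    }
    dir
  }
})

fastTrainConfig <- function(maxEpochs = 15, seed = 1)
  trainConfig(maxEpochs = maxEpochs, seed = seed)
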