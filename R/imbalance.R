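#' SMOTE configuration
#'
#' @param targetRatio desired minority/majority ratio after synthesis
#'   (default 0.5, i.e. the minority class is brought up to half the
#'   majority class, a 33.3% minority fraction).
#' @param kNeighbors number of nearest minority neighbors to interpolate
#'   toward (default 5).
#' @param seed RNG seed.
#' @return A `SmoteConfig` list.
#' @export
smoteConfig <- function(targetRatio = 0.5, kNeighbors = 5, seed = NULL) {
  if (targetRatio <= 0 || targetRatio > 1)
    .stopf("targetRatio must be in (0, 1]")
  if (!.isCount(kNeighbors) || kNeighbors < 1)
    .stopf("kNeighbors must be a count >= 1")
  structure(list(targetRatio = targetRatio,
                 kNeighbors = as.integer(kNeighbors), seed = seed),
            class = "SmoteConfig")
}

#' Synthesize minority-class windows by SMOTE interpolation
#'
#' Classic synthetic minority oversampling: each synthetic sample is
#' `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`, where `x_i` is a
#' uniformly drawn minority window and `x_nn` one of its `k` nearest
#' minority neighbors (Euclidean distance on flattened windows, excluding
#' itself). Synthesis provenance (parent index, neighbor index, `u`) is
#' attached as attribute `"provenance"` so the interpolation geometry can be
#' audited.
#'
#' @param x minority windows, an `N x T x C` array with `N > k`.
#' @param nNew number of synthetic windows to create.
#' @param k neighborhood size.
#' @param seed RNG seed.
#' @return An `nNew x T x C` array of synthetic windows.
#' @export
smoteSynthesize <- function(x, nNew, k = 5, seed = NULL) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1]
  if (n <= k)
    .stopf("SMOTE needs more minority samples (%d) than neighbors (k = %d)",
           n, k)
  if (nNew == 0) return(x[integer(0), , , drop = FALSE])
  flat <- matrix(x, n, dim(x)[2] * dim(x)[3])

  # squared Euclidean distances via the Gram matrix
  sq <- rowSums(flat^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(flat)
  diag(d2) <- Inf
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) knn[i, ] <- order(d2[i, ])[seq_len(k)]

  .withSeed(seed, {
    parent <- sample.int(n, nNew, replace = TRUE)
    pick <- sample.int(k, nNew, replace = TRUE)
    u <- stats::runif(nNew)
    nbr <- knn[cbind(parent, pick)]
    synth <- flat[parent, , drop = FALSE] +
      u * (flat[nbr, , drop = FALSE] - flat[parent, , drop = FALSE])
    out <- array(synth, c(nNew, dim(x)[2], dim(x)[3]))
    attr(out, "provenance") <- data.frame(parent = parent, neighbor = nbr,
                                          u = u)
    out
  })
}

#' Rebalance a training set by SMOTE oversampling
#'
#' If the minority/majority ratio is below `targetRatio`, synthesizes exactly
#' `ceiling(targetRatio * n_majority) - n_minority` minority windows so the
#' resulting minority fraction is `targetRatio / (1 + targetRatio)` (33.3%
#' at the default ratio 0.5); otherwise the data pass through unchanged.
#' Apply to the training split only — never to validation or test data.
#'
#' @param x training windows (`N x T x C`).
#' @param y binary labels (1 = functional).
#' @param subjectIds optional provenance tags; synthetic windows inherit
#'   their parent's tag.
#' @param config a [smoteConfig()].
#' @return A list with `x`, `y`, `subjectIds`, `synthetic` (logical mask of
#'   appended windows) and `nSynthetic`.
#' @export
rebalanceTrainingSet <- function(x, y, subjectIds = NULL,
                                 config = smoteConfig()) {
  stopifnot(inherits(config, "SmoteConfig"))
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0))
    .stopf("single-class training data: cannot rebalance")
  minLab <- if (counts["1"] <= counts["0"]) 1L else 0L
  nMin <- sum(y == minLab)
  nMaj <- length(y) - nMin
  nNew <- as.integer(ceiling(config$targetRatio * nMaj) - nMin)
  if (nNew <= 0)
    return(list(x = x, y = y, subjectIds = subjectIds,
                synthetic = rep(FALSE, length(y)), nSynthetic = 0L))
  minIdx <- which(y == minLab)
  synth <- smoteSynthesize(x[minIdx, , , drop = FALSE], nNew,
                           k = config$kNeighbors, seed = config$seed)
  prov <- attr(synth, "provenance")
  xOut <- array(0, c(dim(x)[1] + nNew, dim(x)[2], dim(x)[3]))
  xOut[seq_len(dim(x)[1]), , ] <- x
  xOut[dim(x)[1] + seq_len(nNew), , ] <- synth
  sidOut <- NULL
  if (!is.null(subjectIds))
    sidOut <- c(subjectIds, subjectIds[minIdx][prov$parent])
  list(x = xOut, y = c(y, rep(minLab, nNew)), subjectIds = sidOut,
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, nNew)),
       nSynthetic = nNew)
}
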