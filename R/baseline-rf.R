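#' Handcrafted time-domain features for one window
#'
#' The standard human-activity-recognition feature set the random-forest
#' baseline consumes: per channel mean, standard deviation, min, max and
#' RMS; per arm (triple of channels) the signal magnitude area (mean of
#' summed absolute accelerations) and the mean and standard deviation of the
#' acceleration magnitude; plus all pairwise channel correlations. For a
#' 3-channel window this yields 21 features (15 + 1 + 2 + 3).
#'
#' @param window numeric `T x C` matrix (C = 3 or 6).
#' @return Named numeric feature vector; constant channels contribute 0
#'   correlation with a warning.
#' @export
extractFeatures <- function(window) {
  if (anyNA(window)) .stopf("NaN/NA in window")
  C_ <- ncol(window)
  stopifnot(C_ %in% c(3L, 6L))
  chNames <- if (C_ == 3) c("x", "y", "z")
             else c("x1", "y1", "z1", "x2", "y2", "z2")
  feats <- c()
  for (ch in seq_len(C_)) {
    v <- window[, ch]
    f <- c(mean(v), stats::sd(v), min(v), max(v), sqrt(mean(v^2)))
    names(f) <- paste0(chNames[ch], c("_mean", "_sd", "_min", "_max", "_rms"))
    feats <- c(feats, f)
  }
  nArms <- C_ / 3L
  for (arm in seq_len(nArms)) {
    cols <- (arm - 1L) * 3L + 1:3
    mag <- sqrt(rowSums(window[, cols, drop = FALSE]^2))
    f <- c(mean(rowSums(abs(window[, cols, drop = FALSE]))),
           mean(mag), stats::sd(mag))
    names(f) <- paste0("arm", arm, c("_sma", "_magmean", "_magsd"))
    feats <- c(feats, f)
  }
  prs <- utils::combn(C_, 2)
  consts <- apply(window, 2, function(v) stats::sd(v) == 0)
  if (any(consts))
    warning("constant channel(s): correlations involving them reported as 0")
  cors <- apply(prs, 2, function(pr) {
    if (consts[pr[1]] || consts[pr[2]]) return(0)
    stats::cor(window[, pr[1]], window[, pr[2]])
  })
  names(cors) <- apply(prs, 2, function(pr)
    paste0("cor_", chNames[pr[1]], "_", chNames[pr[2]]))
  c(feats, cors)
}

#' Feature matrix for a window array
#'
#' @param x `N x T x C` window array or [WindowedDataset-class].
#' @return `N x p` feature matrix.
#' @export
extractFeatureMatrix <- function(x) {
  if (is(x, "WindowedDataset")) x <- windowArray(x)
  n <- dim(x)[1]
  out <- NULL
  for (i in seq_len(n)) {
    f <- suppressWarnings(extractFeatures(x[i, , ]))
    if (is.null(out)) out <- matrix(0, n, length(f),
                                    dimnames = list(NULL, names(f)))
    out[i, ] <- f
  }
  out
}

#' Random-forest baseline settings
#'
#' @param nTrees number of trees (default 500).
#' @param seed RNG seed for forest growth.
#' @return An `RfSettings` list.
#' @export
rfSettings <- function(nTrees = 500, seed = 1) {
  structure(list(nTrees = as.integer(nTrees), seed = seed),
            class = "RfSettings")
}

# Train/evaluate a random forest on one fold's feature matrices.
.rfFold <- function(trainF, trainY, testF, testY, settings) {
  fit <- .withSeed(settings$seed,
    randomForest::randomForest(x = trainF,
                               y = factor(trainY, levels = c(0, 1)),
                               ntree = settings$nTrees))
  predTr <- as.integer(as.character(stats::predict(fit, trainF)))
  predTe <- as.integer(as.character(stats::predict(fit, testF)))
  list(train = computeMetrics(trainY, predTr),
       val = computeMetrics(testY, predTe))
}
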