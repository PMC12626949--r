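# Independent brute-force oracles. These deliberately use plain loops and
# first-principles definitions, not the package's vectorized code paths.

# Majority vote with ties -> "U", one frame at a time.
oracleConsensus <- function(tracks) {
  n <- length(tracks[[1]])
  a <- length(tracks)
  out <- character(n)
  for (i in seq_len(n)) {
    votes <- vapply(tracks, function(tr) tr[i], "")
    counts <- c(F = sum(votes == "F"), NF = sum(votes == "NF"),
                U = sum(votes == "U"))
    winner <- names(counts)[counts > a / 2]
    out[i] <- if (length(winner) == 1) winner else "U"
  }
  out
}

# Mean pairwise agreement, explicit double loop.
oracleAgreement <- function(tracks) {
  a <- length(tracks)
  tot <- 0
  np <- 0
  for (i in seq_len(a - 1)) {
    for (j in (i + 1):a) {
      tot <- tot + mean(tracks[[i]] == tracks[[j]])
      np <- np + 1
    }
  }
  100 * tot / np
}

# Window tiling by sequential scan: returns per-window labels in order.
oracleTile <- function(labels, wlen) {
  n <- length(labels)
  out <- character(0)
  i <- 1
  while (i <= n) {
    if (labels[i] == "U") { i <- i + 1; next }
    j <- i
    while (j <= n && labels[j] != "U") j <- j + 1   # run is [i, j-1]
    runLen <- j - i
    k <- 0
    while ((k + 1) * wlen <= runLen) {
      win <- labels[(i + k * wlen):(i + (k + 1) * wlen - 1)]
      nf <- sum(win == "F"); nn <- sum(win == "NF")
      if (nf != nn) out <- c(out, if (nf > nn) "F" else "NF")
      k <- k + 1
    }
    i <- j
  }
  out
}

# Confusion counts by explicit tally.
oracleMetrics <- function(yTrue, yPred) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(yTrue)) {
    if (yTrue[i] == 1 && yPred[i] == 1) tp <- tp + 1
    if (yTrue[i] == 0 && yPred[i] == 1) fp <- fp + 1
    if (yTrue[i] == 0 && yPred[i] == 0) tn <- tn + 1
    if (yTrue[i] == 1 && yPred[i] == 0) fn <- fn + 1
  }
  f1 <- function(tp2, fp2, fn2) {
    den <- 2 * tp2 + fp2 + fn2
    if (den == 0) 0 else 2 * tp2 / den
  }
  list(accuracy = (tp + tn) / length(yTrue),
       f1Functional = f1(tp, fp, fn),
       f1Nonfunctional = f1(tn, fn, fp))
}

# All-pairs k nearest neighbors with explicit distance loops.
oracleKnn <- function(flat, k) {
  n <- nrow(flat)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((flat[i, ] - flat[j, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# Type-7 quantile from its defining formula on sorted data.
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Total trainable elements of an initialized weight set (the "framework"
# count, against which the analytic countParameters() is checked).
oracleWeightCount <- function(spec) {
  w <- armetry:::.initWeights(spec)
  trainable <- armetry:::.TRAINABLE
  sum(vapply(w[trainable], length, 1L))
}

# Independent re-run of the learning-rate plateau schedule from a recorded
# validation-loss history (drop by `factor` after `patience` flat epochs).
oracleLrSchedule <- function(valLoss, lr0, factor = 0.1, patience = 10,
                             minDelta = 1e-4) {
  lr <- lr0
  best <- Inf
  wait <- 0
  out <- numeric(length(valLoss))
  for (e in seq_along(valLoss)) {
    out[e] <- lr
    if (valLoss[e] < best - minDelta) {
      best <- valLoss[e]
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0
      }
    }
  }
  out
}
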