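# Internal neural-network engine: R-side layer over the compiled kernels.
#
# Weight initialization, minibatch shuffling and the epoch/callback schedule
# live in R; src/nn.cpp implements one epoch of minibatch SGD (im2col
# convolutions on BLAS, batch norm, inverted dropout, Adam) and inference.
# All randomness (Glorot init, shuffling, dropout masks) is drawn from R's
# RNG, so a fixed seed reproduces training exactly on a given machine.

# Glorot-uniform initial kernel.
.glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Kernels are (9*chIn) x filters matrices, rows grouped by 3x3 offset
# (channel fastest within each offset); biases/BN parameters are per-filter.
.initWeights <- function(spec) {
  C_ <- spec$inputShape[2]
  f1 <- spec$convBlocks[[1]]$filters
  f2 <- spec$convBlocks[[2]]$filters
  P <- spec$inputShape[1] * C_
  u1 <- spec$denseBlocks[[1]]$units
  u2 <- spec$denseBlocks[[2]]$units
  list(
    conv1_W = .glorot(9L, f1, 9L, 9L * f1),
    conv1_b = numeric(f1),
    bn1_gamma = rep(1, f1), bn1_beta = numeric(f1),
    bn1_rmean = numeric(f1), bn1_rvar = rep(1, f1),
    conv2_W = .glorot(9L * f1, f2, 9L * f1, 9L * f2),
    conv2_b = numeric(f2),
    bn2_gamma = rep(1, f2), bn2_beta = numeric(f2),
    bn2_rmean = numeric(f2), bn2_rvar = rep(1, f2),
    dense1_W = .glorot(P * f2, u1, P * f2, u1),
    dense1_b = numeric(u1),
    dense2_W = .glorot(u1, u2, u1, u2),
    dense2_b = numeric(u2),
    head_W = .glorot(u2, 1L, u2, 1L),
    head_b = numeric(1L)
  )
}

.TRAINABLE <- c("conv1_W", "conv1_b", "bn1_gamma", "bn1_beta",
                "conv2_W", "conv2_b", "bn2_gamma", "bn2_beta",
                "dense1_W", "dense1_b", "dense2_W", "dense2_b",
                "head_W", "head_b")

.adamInit <- function(w) {
  st <- list(t = 0)
  for (nm in .TRAINABLE) {
    z <- as.matrix(w[[nm]]) * 0   # biases as column matrices for the kernels
    st[[paste0("m_", nm)]] <- z
    st[[paste0("v_", nm)]] <- z
  }
  st
}

.bceLoss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.l2Penalty <- function(w, spec) {
  l2 <- spec$denseBlocks[[1]]$l2
  l2 * (sum(w$dense1_W^2) + sum(w$dense2_W^2))
}

# Flatten an (N, T, C) window array to one column per window (position
# fastest: time within channel), the layout the compiled kernels expect.
.flattenWindows <- function(X) {
  N <- dim(X)[1]; T_ <- dim(X)[2]; C_ <- dim(X)[3]
  matrix(aperm(X, c(2L, 3L, 1L)), T_ * C_, N)
}

# One training epoch over shuffled minibatches; returns updated weights,
# optimizer state and summed training loss/correct counts.
.nnEpoch <- function(w, st, lr, Xflat, y, T_, C_, perm, config, spec) {
  dropSeed <- sample.int(2147483647L, 1L)  # epoch dropout stream, from R RNG
  .nnEpochCpp(w, st, lr, Xflat, y, T_, C_, as.integer(perm),
              config$batchSize, as.double(dropSeed),
              spec$convBlocks[[1]]$dropout, spec$convBlocks[[2]]$dropout,
              spec$denseBlocks[[1]]$dropout, spec$denseBlocks[[2]]$dropout,
              spec$denseBlocks[[1]]$l2, spec$bnEps, spec$bnMomentum)
}

# Inference over an (N, T, C) array; dropout off, batch norm running stats.
.nnPredict <- function(w, spec, X, chunk = 256L) {
  T_ <- dim(X)[2]; C_ <- dim(X)[3]
  as.vector(.nnPredictCpp(w, .flattenWindows(X), T_, C_, spec$bnEps,
                          as.integer(chunk)))
}
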