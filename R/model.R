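#' Describe the convolutional/dense classifier architecture
#'
#' Builds the architecture description for the per-window binary classifier:
#' two 3x3 convolution blocks (16 then 32 filters, each followed by batch
#' normalization, ReLU and 20% dropout), a flatten step, two dense blocks of
#' 64 ReLU units with L2 weight decay (lambda = 1e-3) and 30% dropout, and a
#' single sigmoid output unit giving the probability that the window is
#' functional. Convolutions use "same" padding on both the time and channel
#' axes so the 3x3 kernel is valid for 3-channel (single-arm) as well as
#' 6-channel (bilateral) inputs.
#'
#' @param inputShape integer vector `(T, C, 1)`: 60 time samples (2 s at
#'   30 Hz), 3 or 6 channels, one image plane.
#' @return An `ArchitectureSpec` list describing every layer; used by
#'   [trainModel()] and [countParameters()].
#' @examples
#' spec <- buildArchitecture(c(60, 3, 1))
#' countParameters(spec)
#' @export
buildArchitecture <- function(inputShape) {
  if (length(inputShape) == 2L) inputShape <- c(inputShape, 1L)
  if (length(inputShape) != 3L || inputShape[3] != 1L)
    .stopf("inputShape must be (T, C, 1), got (%s)",
           paste(inputShape, collapse = ", "))
  if (inputShape[1] != 60L)
    .stopf("unsupported window length %d: windows must be 60 samples (2 s at 30 Hz)",
           inputShape[1])
  if (!inputShape[2] %in% c(3L, 6L))
    .stopf("unsupported channel count %d: 3 (single-arm) or 6 (combined) supported",
           inputShape[2])
  structure(list(
    inputShape = as.integer(inputShape),
    padding = "same",
    convBlocks = list(
      list(filters = 16L, kernel = c(3L, 3L), dropout = 0.20),
      list(filters = 32L, kernel = c(3L, 3L), dropout = 0.20)
    ),
    denseBlocks = list(
      list(units = 64L, l2 = 1e-3, dropout = 0.30),
      list(units = 64L, l2 = 1e-3, dropout = 0.30)
    ),
    head = list(units = 1L, activation = "sigmoid"),
    bnEps = 1e-3,
    bnMomentum = 0.99
  ), class = "ArchitectureSpec")
}

#' Count model parameters analytically
#'
#' Layer-by-layer analytic parameter count: a convolution contributes
#' `kh*kw*c_in*f + f` weights, a batch-normalization layer `2f` trainable
#' (gamma, beta) plus `2f` non-trainable (running mean/variance), and a dense
#' layer `in*out + out`.
#'
#' @param spec an `ArchitectureSpec` from [buildArchitecture()].
#' @return Integer count of trainable parameters, with attribute
#'   `nonTrainable` holding the non-trainable (running statistic) count.
#' @export
countParameters <- function(spec) {
  stopifnot(inherits(spec, "ArchitectureSpec"))
  T_ <- spec$inputShape[1]; C_ <- spec$inputShape[2]
  f1 <- spec$convBlocks[[1]]$filters
  f2 <- spec$convBlocks[[2]]$filters
  u1 <- spec$denseBlocks[[1]]$units
  u2 <- spec$denseBlocks[[2]]$units
  conv1 <- 3L * 3L * 1L * f1 + f1
  conv2 <- 3L * 3L * f1 * f2 + f2
  bnTrain <- 2L * f1 + 2L * f2
  bnFrozen <- 2L * f1 + 2L * f2
  flat <- T_ * C_ * f2                      # "same" padding keeps T x C
  dense1 <- flat * u1 + u1
  dense2 <- u1 * u2 + u2
  head <- u2 * 1L + 1L
  total <- conv1 + conv2 + bnTrain + dense1 + dense2 + head
  structure(as.integer(total), nonTrainable = as.integer(bnFrozen))
}

#' Training configuration
#'
#' The training schedule: Adam with initial learning rate 1e-3, binary
#' cross-entropy, batch size 64, up to 700 epochs, learning rate multiplied
#' by 0.1 when the validation loss has not improved for 10 epochs, and early
#' stopping with patience 20 monitoring validation accuracy, restoring the
#' best weights seen.
#'
#' @param batchSize minibatch size.
#' @param maxEpochs maximum number of epochs.
#' @param lrInit initial Adam learning rate.
#' @param plateauFactor multiplicative learning-rate drop on plateau.
#' @param plateauPatience epochs of flat validation loss before a drop.
#' @param plateauMinDelta minimum validation-loss improvement that resets the
#'   plateau counter.
#' @param stopPatience epochs of flat validation accuracy before stopping.
#' @param restoreBest restore the best-validation-epoch weights at the end.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param verbose print a line per epoch.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(batchSize = 64L, maxEpochs = 700L, lrInit = 1e-3,
                        plateauFactor = 0.1, plateauPatience = 10L,
                        plateauMinDelta = 1e-4, stopPatience = 20L,
                        restoreBest = TRUE, seed = NULL, verbose = FALSE) {
  if (batchSize < 1L) .stopf("batchSize must be >= 1")
  if (plateauPatience >= stopPatience)
    .stopf("plateau patience (%d) must be smaller than early-stop patience (%d)",
           plateauPatience, stopPatience)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), lrInit = lrInit,
                 plateauFactor = plateauFactor,
                 plateauPatience = as.integer(plateauPatience),
                 plateauMinDelta = plateauMinDelta,
                 stopPatience = as.integer(stopPatience),
                 restoreBest = isTRUE(restoreBest), seed = seed,
                 verbose = isTRUE(verbose)), class = "TrainConfig")
}

#' Train the classifier
#'
#' Trains the conv/dense classifier on scaled windows with Adam and binary
#' cross-entropy, monitoring a held-out validation set each epoch. The
#' learning rate drops by the plateau factor after `plateauPatience` epochs
#' without validation-loss improvement; training halts once validation
#' accuracy has not improved for `stopPatience` epochs, and the weights from
#' the best validation epoch are restored.
#'
#' @param x training windows: numeric array `N x 60 x C` (already scaled,
#'   see [fitScaler()]).
#' @param y training labels, binary (1 = functional).
#' @param valX,valY validation windows and labels, monitored each epoch.
#' @param config a [trainConfig()].
#' @return A [TrainedModel-class] with fitted weights and per-epoch history
#'   (`loss`, `accuracy`, `val_loss`, `val_accuracy`, `lr`).
#' @export
trainModel <- function(x, y, valX, valY, config = trainConfig()) {
  stopifnot(inherits(config, "TrainConfig"))
  y <- as.numeric(y); valY <- as.numeric(valY)
  if (length(dim(x)) != 3L || dim(x)[1] != length(y))
    .stopf("x must be an N x T x C array aligned with y")
  if (length(unique(y)) < 2L)
    .stopf(paste0("training data contains a single class; rebalance first ",
                  "(see rebalanceTrainingSet())"))
  spec <- buildArchitecture(c(dim(x)[2], dim(x)[3], 1L))
  T_ <- dim(x)[2]; C_ <- dim(x)[3]; N <- dim(x)[1]

  res <- .withSeed(config$seed, {
    w <- .initWeights(spec)
    st <- .adamInit(w)
    lr <- config$lrInit
    Xflat <- .flattenWindows(x)

    hist <- vector("list", config$maxEpochs)
    bestAcc <- -Inf; bestW <- NULL; bestEpoch <- 0L; stopWait <- 0L
    bestLoss <- Inf; plateauWait <- 0L
    epochsRun <- 0L

    for (epoch in seq_len(config$maxEpochs)) {
      perm <- sample.int(N)
      r <- .nnEpoch(w, st, lr, Xflat, y, T_, C_, perm, config, spec)
      w <- r$w; st <- r$adam
      lossSum <- r$lossSum; accSum <- r$accSum
      valP <- .nnPredict(w, spec, valX)
      valLoss <- .bceLoss(valP, valY) + .l2Penalty(w, spec)
      valAcc <- mean((valP >= 0.5) == (valY == 1))
      hist[[epoch]] <- data.frame(
        epoch = epoch, loss = lossSum / N, accuracy = accSum / N,
        val_loss = valLoss, val_accuracy = valAcc, lr = lr)
      epochsRun <- epoch
      if (config$verbose)
        message(sprintf(
          "epoch %3d loss %.4f acc %.4f val_loss %.4f val_acc %.4f lr %g",
          epoch, lossSum / N, accSum / N, valLoss, valAcc, lr))

      if (valAcc > bestAcc) {
        bestAcc <- valAcc; bestEpoch <- epoch; stopWait <- 0L
        if (config$restoreBest) bestW <- w
      } else stopWait <- stopWait + 1L

      if (valLoss < bestLoss - config$plateauMinDelta) {
        bestLoss <- valLoss; plateauWait <- 0L
      } else {
        plateauWait <- plateauWait + 1L
        if (plateauWait >= config$plateauPatience) {
          lr <- lr * config$plateauFactor
          plateauWait <- 0L
        }
      }
      if (stopWait >= config$stopPatience) break
    }
    list(w = if (config$restoreBest && !is.null(bestW)) bestW else w,
         hist = do.call(rbind, hist[seq_len(epochsRun)]),
         epochsRun = epochsRun, bestEpoch = bestEpoch)
  })

  new("TrainedModel", spec = unclass(spec), weights = res$w,
      history = res$hist, epochsRun = res$epochsRun)
}

#' Predict per-window functional probabilities
#'
#' Runs the fitted network in inference mode (dropout off, batch
#' normalization using its running statistics), so predictions are
#' deterministic for fixed weights. Windows must be scaled with the same
#' scaler used for the model's training data.
#'
#' @param model a [TrainedModel-class].
#' @param windows numeric array `N x 60 x C` or a [WindowedDataset-class].
#' @return Numeric vector of probabilities in `[0, 1]` that each window is
#'   functional.
#' @export
predictProba <- function(model, windows) {
  stopifnot(is(model, "TrainedModel"))
  if (is(windows, "WindowedDataset")) windows <- windowArray(windows)
  spec <- structure(model@spec, class = "ArchitectureSpec")
  d <- dim(windows)
  if (length(d) != 3L || d[2] != spec$inputShape[1] || d[3] != spec$inputShape[2])
    .stopf("window shape (%s) does not match model input (%s)",
           paste(d[-1], collapse = "x"),
           paste(spec$inputShape[1:2], collapse = "x"))
  .nnPredict(model@weights, spec, windows)
}

#' Threshold probabilities into class labels
#'
#' @param p probabilities from [predictProba()].
#' @param threshold decision threshold; `p >= threshold` maps to 1
#'   (functional).
#' @return Integer vector of 0/1 labels.
#' @export
classifyProb <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1)) .stopf("probabilities must lie in [0, 1]")
  as.integer(p >= threshold)
}
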