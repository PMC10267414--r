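# Training protocol: pixelwise cross-entropy, Adam with a StepLR schedule,
# per-epoch validation by mean foreground Dice, best-on-validation model
# selection, and k-fold cross-validation.

#' Training configuration
#'
#' @param learningRate Initial Adam learning rate (default 0.002).
#' @param maxEpochs Number of epochs; training always runs the full budget
#'   and the best-on-validation weights are kept (no early stopping).
#' @param batchSize Images per gradient step (gradient averaging).
#' @param steplrStep Epoch interval of the StepLR decay.
#' @param steplrGamma Multiplicative decay factor in (0, 1].
#' @param seed Master seed; folds, augmentation and initialization all
#'   derive their streams from it.
#' @param foldCount Folds for [crossValidate()] (default 4).
#' @param crop Optional `c(height, width)` applied through [cropOrPad()]
#'   before feeding the network (dims must be divisible by 8); `NULL`
#'   leaves inputs unchanged.
#' @param augment An [augmentationConfig()] applied to training samples
#'   only, or `NULL` for none.
#' @return A validated list of class `"trainConfig"`.
#' @export
trainConfig <- function(learningRate = 0.002, maxEpochs = 300L, batchSize = 4L,
                        steplrStep = 50L, steplrGamma = 0.5, seed = 1L,
                        foldCount = 4L, crop = NULL, augment = NULL) {
  if (learningRate <= 0) stop("learningRate must be > 0")
  if (maxEpochs < 1L) stop("maxEpochs must be >= 1")
  if (steplrGamma <= 0 || steplrGamma > 1) stop("steplrGamma must lie in (0, 1]")
  if (!is.null(augment) && !inherits(augment, "augmentationConfig"))
    stop("augment must be an augmentationConfig or NULL")
  structure(list(learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 steplrStep = as.integer(steplrStep), steplrGamma = steplrGamma,
                 seed = as.integer(seed), foldCount = as.integer(foldCount),
                 crop = crop, augment = augment),
            class = "trainConfig")
}

#' Learning rate of the StepLR schedule at a given epoch
#'
#' Closed form `lr0 * gamma^floor((epoch - 1) / step)` for 1-based epochs:
#' the rate decays by `gamma` every `step` epochs.
#'
#' @param config A [trainConfig()].
#' @param epoch 1-based epoch number.
#' @return The learning rate in effect during that epoch.
#' @export
learningRateAt <- function(config, epoch) {
  config$learningRate * config$steplrGamma^((epoch - 1) %/% config$steplrStep)
}

#' Pixelwise cross-entropy loss
#'
#' Mean over pixels of the negative log-softmax of the true class.
#'
#' @param logits `H x W x C` array (or `(H*W) x C` matrix) of class scores.
#' @param target Integer `H x W` matrix (or vector) of labels in `0..C-1`.
#' @return Non-negative scalar loss.
#' @export
crossEntropyLoss <- function(logits, target) {
  z <- if (is.matrix(logits)) logits else asFeatureMatrix(logits)
  t <- as.integer(target)
  if (length(t) != nrow(z))
    stop("target must have one label per pixel")
  if (min(t) < 0 || max(t) >= ncol(z))
    stop(sprintf("target labels must lie in 0..%d", ncol(z) - 1L))
  ceLossGrad(z, t)$loss
}

ceLossGrad <- function(z, t) {
  n <- nrow(z)
  zmax <- apply(z, 1L, max)
  zs <- z - zmax
  lse <- log(rowSums(exp(zs)))
  trueIdx <- cbind(seq_len(n), t + 1L)
  loss <- mean(lse - zs[trueIdx])
  p <- exp(zs - lse)
  p[trueIdx] <- p[trueIdx] - 1
  list(loss = loss, dlogits = p / n)
}

## ---- Adam ------------------------------------------------------------------

# Recursion over the gradient structure (which contains only trainable
# leaves); parameter entries without a gradient (structural constants such
# as kernel sizes) are left untouched.
adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state))
    state <- list(t = 0L,
                  m = mapNested(function(g) g * 0, grads),
                  v = mapNested(function(g) g * 0, grads))
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (key in keys) {
        r <- rec(p[[key]], g[[key]], m[[key]], v[[key]])
        p[[key]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = t, m = r$m, v = r$v))
}

## ---- validation metric ------------------------------------------------------

#' Mean foreground Dice between predicted and true masks
#'
#' Mean of the per-class Dice scores over the foreground classes, excluding
#' classes absent from both masks.
#'
#' @param pred,true Integer label matrices of equal shape.
#' @param nClasses Total class count C.
#' @return Scalar in \[0, 1\] (`NaN` when no foreground class is present).
#' @export
meanForegroundDice <- function(pred, true, nClasses) {
  cc <- confusionCounts(pred, true, nClasses)
  tp <- cc@tp[-1L]; fp <- cc@fp[-1L]; fn <- cc@fn[-1L]
  present <- (tp + fp + fn) > 0
  mean(2 * tp[present] / (2 * tp[present] + fp[present] + fn[present]))
}

prepScan <- function(scan, crop) {
  if (!is.null(crop)) scan <- cropOrPad(scan, crop)
  scan
}

modelValDice <- function(params, cfg, valScans, crop) {
  d <- vapply(valScans, function(s) {
    s <- prepScan(s, crop)
    fw <- netForward(params, cfg, s@image, keepCache = FALSE)
    pred <- matrix(max.col(fw$logits, ties.method = "first") - 1L,
                   nrow(s@image), ncol(s@image))
    meanForegroundDice(pred, s@mask, cfg$nClasses)
  }, numeric(1))
  mean(d)
}

## ---- training loop ----------------------------------------------------------

#' Train on one fold
#'
#' Runs the full training protocol on a train/validation split: per-epoch
#' shuffling, optional augmentation of training samples only, minibatch
#' gradient averaging, Adam updates under the StepLR schedule, and
#' best-on-validation (mean foreground Dice) weight selection.  Fully
#' deterministic given the configuration seed.
#'
#' @param trainScans,valScans Non-empty lists of [AnnotatedBScan-class].
#' @param netConfig A [networkConfig()].
#' @param config A [trainConfig()].
#' @param verbose Print a per-epoch line.
#' @return A list of class `"trainState"` with `epoch`, `bestValMetric`,
#'   `bestModel` (a [SegmentationModel-class]), `finalModel` and `history`
#'   (data frame: epoch, lr, trainLoss, valDice).
#' @export
trainFold <- function(trainScans, valScans, netConfig = networkConfig(),
                      config = trainConfig(), verbose = FALSE) {
  if (length(trainScans) == 0L || length(valScans) == 0L)
    stop("training and validation splits must be non-empty")
  cfgN <- if (inherits(netConfig, "networkConfig")) unclass(netConfig) else netConfig
  params <- buildNetwork(`class<-`(cfgN, "networkConfig"), seed = config$seed)@params
  state <- NULL
  best <- list(metric = -Inf, params = NULL, epoch = 0L)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        trainLoss = numeric(), valDice = numeric())
  nTrain <- length(trainScans)
  for (epoch in seq_len(config$maxEpochs)) {
    lr <- learningRateAt(config, epoch)
    set.seed(config$seed + 7919L * epoch)
    ord <- sample.int(nTrain)
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1L, nTrain, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, nTrain)]
      gradSum <- NULL
      batchLoss <- 0
      for (i in idx) {
        s <- trainScans[[i]]
        if (!is.null(config$augment))
          s <- augmentSample(s, config$augment,
                             rngSeed = config$seed + 104729L * epoch + i)
        s <- prepScan(s, config$crop)
        fw <- netForward(params, cfgN, s@image, keepCache = TRUE)
        lg <- ceLossGrad(fw$logits, as.integer(s@mask))
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d (sample %d); aborting",
                       epoch, i))
        batchLoss <- batchLoss + lg$loss
        bw <- netBackward(params, cfgN, fw$cache, lg$dlogits)
        gradSum <- if (is.null(gradSum)) bw$grads else sumNested(gradSum, bw$grads)
      }
      grads <- mapNested(function(g) g / length(idx), gradSum)
      up <- adamStep(params, grads, state, lr)
      params <- up$params
      state <- up$state
      epochLoss <- epochLoss + batchLoss / length(idx)
      nb <- nb + 1L
    }
    valDice <- modelValDice(params, cfgN, valScans, config$crop)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                trainLoss = epochLoss / nb, valDice = valDice))
    if (is.finite(valDice) && valDice > best$metric)
      best <- list(metric = valDice, params = params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val Dice %.4f",
                      epoch, lr, epochLoss / nb, valDice))
  }
  structure(list(epoch = config$maxEpochs,
                 bestValMetric = best$metric,
                 bestEpoch = best$epoch,
                 bestModel = new("SegmentationModel", config = cfgN,
                                 params = best$params),
                 finalModel = new("SegmentationModel", config = cfgN,
                                  params = params),
                 history = history),
            class = "trainState")
}

#' k-fold cross-validation
#'
#' Splits the pool with [makeFolds()], trains each fold with [trainFold()],
#' evaluates each fold's best model on its validation samples and reports
#' per-class Dice aggregated both across folds (mean +/- sd of fold means)
#' and across individual validation images.
#'
#' @param scans Named list of [AnnotatedBScan-class] (the training pool).
#' @param k Number of folds (defaults to the configuration's `foldCount`).
#' @param netConfig A [networkConfig()].
#' @param config A [trainConfig()].
#' @return A list with `states` (one `trainState` per fold), `table` (data
#'   frame: class, meanDice, sdDice across folds), `perImage` (data frame
#'   of per-image per-class Dice) and `folds`.
#' @export
crossValidate <- function(scans, k = config$foldCount,
                          netConfig = networkConfig(),
                          config = trainConfig()) {
  ids <- names(scans)
  if (is.null(ids)) stop("scans must be a named list")
  folds <- makeFolds(ids, k, seed = config$seed)
  C <- netConfig$nClasses
  states <- vector("list", length(folds))
  foldClassDice <- matrix(NA_real_, length(folds), C - 1L)
  perImage <- NULL
  for (f in seq_along(folds)) {
    sp <- folds[[f]]
    states[[f]] <- trainFold(scans[trainIds(sp)], scans[valIds(sp)],
                             netConfig, config)
    model <- states[[f]]$bestModel
    dmat <- t(vapply(valIds(sp), function(id) {
      s <- prepScan(scans[[id]], config$crop)
      pred <- predictMask(model, s@image)
      cc <- confusionCounts(pred, s@mask, C)
      dice <- 2 * cc@tp / pmax(2 * cc@tp + cc@fp + cc@fn, .Machine$double.eps)
      dice[(cc@tp + cc@fp + cc@fn) == 0] <- NA_real_
      dice[-1L]
    }, numeric(C - 1L)))
    foldClassDice[f, ] <- colMeans(dmat, na.rm = TRUE)
    perImage <- rbind(perImage,
                      data.frame(fold = f, id = rep(valIds(sp), each = C - 1L),
                                 class = rep(seq_len(C - 1L), length(valIds(sp))),
                                 dice = as.numeric(t(dmat))))
  }
  tab <- data.frame(class = seq_len(C - 1L),
                    meanDice = colMeans(foldClassDice),
                    sdDice = apply(foldClassDice, 2L, stats::sd))
  list(states = states, table = tab, perImage = perImage, folds = folds)
}
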