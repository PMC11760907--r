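## Training loop: Adam on pixel-wise binary cross-entropy, seeded shuffling
## and augmentation, per-epoch validation, best-validation-loss
## checkpointing (first epoch attaining the minimum wins).

#' Train a segmentation model
#'
#' Runs `epochs` epochs of `max(1, floor(n_train / batchSize))` minibatch
#' steps minimizing pixel-wise binary cross-entropy with Adam.  Minibatches
#' are drawn from a per-epoch seeded shuffle (cycling when the batch size
#' exceeds the training set); augmentation, when configured, is applied
#' on the fly with per-draw seeds and never materialized.  Validation
#' metrics are computed on the split's test set at the end of every epoch,
#' and the returned model carries the parameters of the first epoch with
#' the lowest validation loss.
#'
#' @param model a [SegmentationModel-class] (modified in place).
#' @param split a [DatasetSplit-class]; the test set doubles as the
#'   validation set (the reference protocol defines no third split).
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-epoch metric lines.
#' @return list with `model` (best checkpoint) and `history`
#'   (a [TrainingHistory-class]).
#' @export
trainSegmentationModel <- function(model, split, cfg, verbose = FALSE) {
  stopifnot(is(model, "SegmentationModel"), is(cfg, "TrainConfig"))
  if (length(split@train) == 0L) stop("argument error: empty training set")
  sz <- model@spec@inputSize
  if (!all(dim(split@train[[1]]@mask) == sz))
    stop("dimension mismatch: sample size differs from model inputSize")
  runTrainingLoop(
    mod = model@module, cfg = cfg,
    train_inputs = lapply(split@train, sampleImage),
    train_masks = lapply(split@train, sampleMask),
    val_inputs = lapply(split@test, sampleImage),
    val_masks = lapply(split@test, sampleMask),
    n_channels = 3L, augment = cfg@augment, verbose = verbose)
  invisible(list(model = model, history = model@module$last_history))
}

## Shared engine for base-model and meta-model training.  Inputs are H x W x C
## arrays (C = 3 images or C = K stacked predictions); masks are H x W.
runTrainingLoop <- function(mod, cfg, train_inputs, train_masks,
                            val_inputs, val_masks, n_channels,
                            augment = NULL, verbose = FALSE) {
  n <- length(train_inputs)
  steps <- max(1L, n %/% cfg@batchSize)
  hist <- data.frame()
  best_val <- Inf
  best_epoch <- 0L
  best_snap <- paramSnapshot(mod$params)
  best_state <- as.list(mod$state)
  if (cfg@epochs > 0L) {
    seeds <- withr::with_seed(cfg@seed,
                              sample.int(.Machine$integer.max - 1L, cfg@epochs))
    opt <- adamInit(mod$params, lr = cfg@learningRate)
    frozen <- frozenMask(mod)
    for (ep in seq_len(cfg@epochs)) {
      ord <- withr::with_seed(seeds[ep], sample.int(n))
      ord <- rep(ord, length.out = steps * cfg@batchSize)
      ep_loss <- 0
      for (st in seq_len(steps)) {
        idx <- ord[((st - 1L) * cfg@batchSize + 1L):(st * cfg@batchSize)]
        xb <- array(0, c(dim(train_inputs[[1]])[1:2], n_channels, length(idx)))
        yb <- array(0, c(dim(train_masks[[1]]), 1L, length(idx)))
        for (k in seq_along(idx)) {
          xi <- train_inputs[[idx[k]]]
          yi <- train_masks[[idx[k]]]
          if (!is.null(augment)) {
            sm <- augmentSample(
              fundusSample("aug", xi, yi, "synthetic"), augment,
              drawSeed = (seeds[ep] + 131L * st + k) %% .Machine$integer.max)
            xi <- sm@image
            yi <- sm@mask
          }
          xb[, , , k] <- xi
          yb[, , 1L, k] <- yi
        }
        oldtr <- vsSetTraining(TRUE)
        res <- vsWithTape({
          pred <- mod$forward(vsNode(xb))
          opBceLoss(pred, yb)
        })
        vsSetTraining(oldtr)
        loss <- res$value$value
        if (!is.finite(loss))
          stop(sprintf("training diverged: non-finite loss at epoch %d step %d",
                       ep, st))
        vsBackward(res$tape, res$value)
        if (any(frozen)) for (p in mod$params[frozen]) p$grad <- NULL
        adamStep(mod$params, opt)
        zeroGrads(mod$params)
        ep_loss <- ep_loss + loss
      }
      vm <- validationMetrics(mod, val_inputs, val_masks, n_channels)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = ep_loss / steps, val_loss = vm$loss,
        val_acc = vm$acc, val_auc = vm$auc, val_f1 = vm$f1))
      if (verbose)
        message(sprintf("epoch %3d  train BCE %.4f  val BCE %.4f  val F1 %.4f",
                        ep, ep_loss / steps, vm$loss, vm$f1))
      if (is.finite(vm$loss) && vm$loss < best_val) { # strict: first best wins
        best_val <- vm$loss
        best_epoch <- ep
        best_snap <- paramSnapshot(mod$params)
        best_state <- as.list(mod$state)
      }
    }
    paramRestore(mod$params, best_snap)
    for (k in names(best_state)) mod$state[[k]] <- best_state[[k]]
  }
  mod$last_history <- new("TrainingHistory", history = hist,
                          bestEpoch = best_epoch,
                          bestValLoss = if (is.finite(best_val)) best_val else NA_real_)
  invisible(mod$last_history)
}

validationMetrics <- function(mod, val_inputs, val_masks, n_channels,
                              threshold = 0.5, auc_max = 20000L) {
  if (length(val_inputs) == 0L)
    return(list(loss = NA_real_, acc = NA_real_, auc = NA_real_, f1 = NA_real_))
  d <- dim(val_inputs[[1]])[1:2]
  xb <- array(0, c(d, n_channels, length(val_inputs)))
  for (k in seq_along(val_inputs)) xb[, , , k] <- val_inputs[[k]]
  old <- vsSetTraining(FALSE)
  pred <- mod$forward(vsNode(xb))$value
  vsSetTraining(old)
  truth <- unlist(lapply(val_masks, as.numeric), use.names = FALSE)
  pred <- as.numeric(pred)
  rm_ <- ratioMetrics(confusionCounts(pred, truth, threshold))
  auc <- if (length(unique(truth)) < 2L) NA_real_ else
    rocAuc(pred, truth, maxPixels = auc_max)
  list(loss = bce(pred, truth), acc = rm_$acc, auc = auc, f1 = rm_$f1)
}

#' Number of optimizer steps per epoch
#'
#' `max(1, floor(nTrain / batchSize))` — the floor clamps to one full batch
#' when the training set is smaller than the batch size (DRIVE's 20 training
#' images with batch size 32 give one step per epoch).
#'
#' @param nTrain training-set size.
#' @param batchSize minibatch size.
#' @return integer step count.
#' @export
stepsPerEpoch <- function(nTrain, batchSize) {
  max(1L, as.integer(nTrain %/% batchSize))
}
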