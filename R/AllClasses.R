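#' @import methods
NULL

#' One fundus image / vessel mask pair
#'
#' Container for a single training or evaluation sample: an RGB fundus
#' photograph in `[0, 1]` and the matching binary vessel annotation, plus an
#' identifier and a provenance flag (`"real"` for images read from disk,
#' `"synthetic"` for generated ones).  Arrays are row-major H x W (x C),
#' origin top-left.
#'
#' @slot id sample identifier.
#' @slot image H x W x 3 numeric array with values in `[0, 1]`.
#' @slot mask H x W matrix containing only 0 and 1.
#' @slot source `"real"` or `"synthetic"`.
#' @export
setClass("FundusSample",
  representation(id = "character", image = "array", mask = "matrix",
                 source = "character"),
  validity = function(object) {
    msg <- character()
    di <- dim(object@image)
    if (length(di) != 3L || di[3] != 3L) msg <- c(msg, "image must be H x W x 3")
    if (!identical(dim(object@mask), di[1:2]))
      msg <- c(msg, "image and mask must have identical height and width")
    if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must contain only 0 and 1")
    rng <- range(object@image)
    if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "image values must lie in [0, 1]")
    if (!object@source %in% c("real", "synthetic"))
      msg <- c(msg, "source must be 'real' or 'synthetic'")
    if (length(msg)) msg else TRUE
  })

#' Construct a FundusSample
#' @param id sample identifier.
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param mask H x W binary matrix.
#' @param source `"real"` or `"synthetic"`.
#' @return A [FundusSample-class] object.
#' @export
fundusSample <- function(id, image, mask, source = c("real", "synthetic")) {
  new("FundusSample", id = as.character(id), image = image,
      mask = as.matrix(mask), source = match.arg(source))
}

#' Train/test partition of fundus samples
#'
#' @slot train,test lists of [FundusSample-class] objects with disjoint ids.
#' @export
setClass("DatasetSplit",
  representation(train = "list", test = "list"),
  validity = function(object) {
    idt <- vapply(object@train, function(s) s@id, character(1))
    ide <- vapply(object@test, function(s) s@id, character(1))
    if (length(intersect(idt, ide)))
      "train and test id sets must be disjoint" else TRUE
  })

#' Architecture hyperparameters for the four base networks
#'
#' @slot name one of `"unet"`, `"resnet50_seg"`, `"unet_resnet_backbone"`,
#'   `"ctu_net"`.
#' @slot inputSize height/width the network accepts.
#' @slot baseChannels width of the first encoder level; every other layer
#'   scales proportionally, so reduced-width models share the full topology.
#' @slot depth number of encoder levels (U-Net family).
#' @slot pretrainedBackbone whether to load external backbone weights
#'   (a weights file must then be supplied to the loader).
#' @slot transformer list with `n_blocks`, `n_heads`, `mlp_ratio` for the
#'   transformer bottleneck of `"ctu_net"`.
#' @slot ppmDilations dilation rates of the pyramid pooling branches of
#'   `"resnet50_seg"`.
#' @slot upsampling `"transpose"` (up-convolution) or `"bilinear"`
#'   (fixed bilinear + 3x3 conv).
#' @slot seed integer seed for parameter initialization.
#' @export
setClass("ArchitectureSpec",
  representation(name = "character", inputSize = "integer",
                 baseChannels = "integer", depth = "integer",
                 pretrainedBackbone = "logical", transformer = "list",
                 ppmDilations = "integer", upsampling = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    nm <- object@name
    if (!nm %in% c("unet", "resnet50_seg", "unet_resnet_backbone", "ctu_net"))
      msg <- c(msg, "unknown architecture name")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    sz <- object@inputSize
    if (any(sz < 1L)) msg <- c(msg, "inputSize must be positive")
    if (nm %in% c("unet", "ctu_net") && any(sz %% 2L^object@depth != 0L))
      msg <- c(msg, sprintf("inputSize must be divisible by 2^depth = %d",
                            2L^object@depth))
    if (nm %in% c("resnet50_seg", "unet_resnet_backbone") && any(sz %% 32L != 0L))
      msg <- c(msg, "inputSize must be divisible by 32 for ResNet-based models")
    if (nm == "ctu_net") {
      dmod <- object@baseChannels * 2L^object@depth
      if (dmod %% object@transformer$n_heads != 0L)
        msg <- c(msg, sprintf(
          "n_heads (%d) must divide the bottleneck embedding dim (%d)",
          object@transformer$n_heads, dmod))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an ArchitectureSpec
#'
#' @param name architecture name.
#' @param inputSize length-2 integer, image height and width.
#' @param baseChannels first-level width (64 reproduces the canonical
#'   full-size networks; small values give desk-scale models with the same
#'   topology).
#' @param depth encoder depth for the U-Net family.
#' @param pretrainedBackbone load external ResNet50 weights (optional hook;
#'   off by default so everything builds offline).
#' @param transformer transformer bottleneck settings for `"ctu_net"`.
#' @param ppmDilations pyramid-pooling dilation rates for `"resnet50_seg"`.
#' @param upsampling decoder upsampling mode.
#' @param seed initialization seed.
#' @return An [ArchitectureSpec-class] object.
#' @export
architectureSpec <- function(name, inputSize = c(256L, 256L), baseChannels = 64L,
                             depth = 4L, pretrainedBackbone = FALSE,
                             transformer = list(n_blocks = 2L, n_heads = 4L,
                                                mlp_ratio = 4),
                             ppmDilations = c(1L, 2L, 4L),
                             upsampling = c("transpose", "bilinear"),
                             seed = 42L) {
  tr <- utils::modifyList(list(n_blocks = 2L, n_heads = 4L, mlp_ratio = 4),
                          transformer)
  new("ArchitectureSpec", name = name,
      inputSize = rep_len(as.integer(inputSize), 2L),
      baseChannels = as.integer(baseChannels), depth = as.integer(depth),
      pretrainedBackbone = isTRUE(pretrainedBackbone), transformer = tr,
      ppmDilations = as.integer(ppmDilations),
      upsampling = match.arg(upsampling), seed = as.integer(seed))
}

#' A segmentation network: H x W x 3 image in, per-pixel vessel probability out
#'
#' Wraps the architecture description and the trainable state (parameter
#' nodes, batch-norm running statistics, forward closure).  Use
#' [predict()][predict,SegmentationModel-method] for inference and
#' [trainSegmentationModel()] for fitting.
#'
#' @slot spec the [ArchitectureSpec-class].
#' @slot module environment holding parameters and the forward function.
#' @export
setClass("SegmentationModel",
  representation(spec = "ArchitectureSpec", module = "environment"))

#' The stacking meta-model g
#'
#' A two-layer convolutional network (3x3 with `hiddenFilters` filters and
#' ReLU, then 1x1 with a single filter and sigmoid) mapping the stacked base
#' predictions Z(x) to the final probability map.
#'
#' @slot kInputs number of stacked input channels (base models).
#' @slot hiddenFilters width of the 3x3 layer.
#' @slot module environment holding parameters and the forward function.
#' @export
setClass("MetaModel",
  representation(kInputs = "integer", hiddenFilters = "integer",
                 module = "environment"))

#' Channel-stacked base-model predictions Z(x)
#'
#' @slot tensor H x W x K array of per-model vessel probabilities.
#' @slot modelOrder the K base-model names, in channel order; the order is
#'   part of the object's identity.
#' @export
setClass("StackedPredictions",
  representation(tensor = "array", modelOrder = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@tensor)
    if (length(d) != 3L) msg <- c(msg, "tensor must be H x W x K")
    else if (d[3] != length(object@modelOrder))
      msg <- c(msg, "channel count must equal length(modelOrder)")
    if (length(object@modelOrder) < 2L) msg <- c(msg, "need at least 2 models")
    if (length(msg)) msg else TRUE
  })

#' Pixel-wise confusion counts at a threshold
#' @slot tp,tn,fp,fn non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"),
  validity = function(object) {
    if (any(c(object@tp, object@tn, object@fp, object@fn) < 0))
      "counts must be non-negative" else TRUE
  })

#' Evaluation summary for one model on one pixel set
#'
#' The row type of the package's report tables: binary cross-entropy loss,
#' accuracy, sensitivity, specificity, AUC, and F1, micro-averaged over the
#' pooled pixels of all evaluated images.
#'
#' @slot loss pixel-wise binary cross-entropy.
#' @slot acc,sn,sp,auc,f1,precision bounded metrics in `[0, 1]`.
#' @slot threshold binarization threshold used for the count-based metrics.
#' @slot nPixels number of pooled pixels evaluated.
#' @slot flags names of ratio metrics whose 0/0 case was defined as 0.
#' @export
setClass("MetricReport",
  representation(loss = "numeric", acc = "numeric", sn = "numeric",
                 sp = "numeric", auc = "numeric", f1 = "numeric",
                 precision = "numeric", threshold = "numeric",
                 nPixels = "numeric", flags = "character"),
  validity = function(object) {
    b <- c(object@acc, object@sn, object@sp, object@f1, object@precision)
    b <- c(b, object@auc[!is.na(object@auc)])
    if (any(b < 0 | b > 1)) "bounded metrics must lie in [0, 1]" else TRUE
  })

#' Training protocol settings
#'
#' Defaults follow the package's reference protocol: Adam with learning rate
#' 0.01, 500 epochs, batch size 32, checkpoint on best validation loss,
#' `steps_per_epoch = max(1, floor(n_train / batch_size))`.
#'
#' @slot optimizer only `"adam"`.
#' @slot learningRate Adam step size.
#' @slot epochs number of epochs (0 is a no-op).
#' @slot batchSize minibatch size.
#' @slot checkpointMetric only `"val_loss"`.
#' @slot seed seed controlling init-independent training randomness
#'   (shuffling, augmentation draws).
#' @slot augment an [AugmentConfig-class] or `NULL` (no augmentation).
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 epochs = "integer", batchSize = "integer",
                 checkpointMetric = "character", seed = "integer",
                 augment = "ANY"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@optimizer != "adam") msg <- c(msg, "optimizer must be 'adam'")
    if (object@checkpointMetric != "val_loss")
      msg <- c(msg, "checkpointMetric must be 'val_loss'")
    if (length(msg)) msg else TRUE
  })

#' Construct a TrainConfig
#' @param learningRate,epochs,batchSize,seed see [TrainConfig-class].
#' @param optimizer,checkpointMetric fixed to their defaults.
#' @param augment an [AugmentConfig-class] or `NULL`.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(learningRate = 0.01, epochs = 500L, batchSize = 32L,
                        seed = 42L, optimizer = "adam",
                        checkpointMetric = "val_loss", augment = NULL) {
  new("TrainConfig", optimizer = optimizer, learningRate = learningRate,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      checkpointMetric = checkpointMetric, seed = as.integer(seed),
      augment = augment)
}

#' Per-epoch training record
#'
#' @slot history data.frame with one row per epoch (train/validation loss and
#'   metrics).
#' @slot bestEpoch first epoch attaining the minimum validation loss.
#' @slot bestValLoss that minimum.
#' @export
setClass("TrainingHistory",
  representation(history = "data.frame", bestEpoch = "integer",
                 bestValLoss = "numeric"))

#' Synthetic vessel-tree settings
#'
#' Parameters of the recursive random-walk generator that draws a branching
#' vessel tree: each root starts on the field-of-view boundary heading
#' inward; headings are jittered per step; branches spawn with probability
#' `branchProb` at 20-50 degrees and their width shrinks by `widthDecay`, so
#' trees thin from trunks to distal branches as real vasculature does.
#'
#' @slot imageSize height/width of the mask.
#' @slot nRoots number of root vessels entering the field of view.
#' @slot maxDepth maximum number of steps per walk.
#' @slot branchProb per-step probability of spawning a child branch.
#' @slot stepLen stroke length per step, pixels.
#' @slot angleJitterSd s.d. of the per-step heading perturbation, radians.
#' @slot rootWidth starting stroke width, pixels.
#' @slot widthDecay multiplicative width loss at each branching.
#' @slot minWidth walks stop when width falls below this.
#' @slot seed generator seed.
#' @export
setClass("VesselTreeConfig",
  representation(imageSize = "integer", nRoots = "integer", maxDepth = "integer",
                 branchProb = "numeric", stepLen = "numeric",
                 angleJitterSd = "numeric", rootWidth = "numeric",
                 widthDecay = "numeric", minWidth = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@imageSize < 1L)) msg <- c(msg, "imageSize must be positive")
    if (object@nRoots < 1L) msg <- c(msg, "nRoots must be >= 1")
    if (object@minWidth > object@rootWidth)
      msg <- c(msg, "minWidth must not exceed rootWidth")
    if (object@branchProb < 0 || object@branchProb > 1)
      msg <- c(msg, "branchProb must lie in [0, 1]")
    if (object@widthDecay <= 0 || object@widthDecay > 1)
      msg <- c(msg, "widthDecay must lie in (0, 1]")
    if (object@stepLen <= 0 || object@rootWidth <= 0 || object@maxDepth < 1L)
      msg <- c(msg, "size/length fields must be positive")
    if (length(msg)) msg else TRUE
  })

#' Fundus rendering settings
#'
#' Controls how a binary vessel mask is turned into a fundus-like photograph:
#' a circular field of view on a black background, a reddish base tint with a
#' linear illumination gradient, vessels darker than their surroundings by
#' `vesselContrast`, and additive Gaussian noise.
#'
#' @slot fovRadiusFrac field-of-view radius as a fraction of `min(H, W) / 2`.
#' @slot backgroundLevel base intensity inside the field of view.
#' @slot vesselContrast how much darker vessels are than background.
#' @slot noiseSd s.d. of the additive pixel noise.
#' @slot illuminationGradient amplitude of the linear shading ramp.
#' @slot seed noise seed.
#' @export
setClass("FundusRenderConfig",
  representation(fovRadiusFrac = "numeric", backgroundLevel = "numeric",
                 vesselContrast = "numeric", noiseSd = "numeric",
                 illuminationGradient = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 1)
      msg <- c(msg, "fovRadiusFrac must lie in (0, 1]")
    if (object@vesselContrast < 0) msg <- c(msg, "vesselContrast must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
      msg <- c(msg, "backgroundLevel must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Geometric augmentation settings
#'
#' The training-time augmentation policy: random rotations up to 15 degrees,
#' width/height shifts up to 10\%, zoom up to 20\% (scale factor in
#' `[0.8, 1.2]`), and horizontal flips with probability one half.  One draw
#' is applied with identical geometry to image (bilinear) and mask (nearest,
#' re-binarized).
#'
#' @slot maxRotationDeg rotation range, degrees.
#' @slot shiftFrac shift range as a fraction of each dimension.
#' @slot maxZoomFrac zoom range; scale is uniform in `1 +/- maxZoomFrac`.
#' @slot hflip allow horizontal flips.
#' @slot seed default seed (per-draw seeds override).
#' @export
setClass("AugmentConfig",
  representation(maxRotationDeg = "numeric", shiftFrac = "numeric",
                 maxZoomFrac = "numeric", hflip = "logical", seed = "integer"))

#' @rdname VesselTreeConfig-class
#' @param imageSize,nRoots,maxDepth,branchProb,stepLen,angleJitterSd,rootWidth,widthDecay,minWidth,seed see slots.
#' @return A [VesselTreeConfig-class] object.
#' @export
vesselTreeConfig <- function(imageSize = c(256L, 256L), nRoots = 4L,
                             maxDepth = 40L, branchProb = 0.12,
                             stepLen = max(3, round(min(imageSize) / 40)),
                             angleJitterSd = 0.25,
                             rootWidth = max(2, round(min(imageSize) / 55)),
                             widthDecay = 0.75, minWidth = 1, seed = 42L) {
  new("VesselTreeConfig", imageSize = rep_len(as.integer(imageSize), 2L),
      nRoots = as.integer(nRoots), maxDepth = as.integer(maxDepth),
      branchProb = branchProb, stepLen = stepLen,
      angleJitterSd = angleJitterSd, rootWidth = rootWidth,
      widthDecay = widthDecay, minWidth = minWidth, seed = as.integer(seed))
}

#' @rdname FundusRenderConfig-class
#' @param fovRadiusFrac,backgroundLevel,vesselContrast,noiseSd,illuminationGradient,seed see slots.
#' @return A [FundusRenderConfig-class] object.
#' @export
fundusRenderConfig <- function(fovRadiusFrac = 0.95, backgroundLevel = 0.55,
                               vesselContrast = 0.35, noiseSd = 0.03,
                               illuminationGradient = 0.08, seed = 42L) {
  new("FundusRenderConfig", fovRadiusFrac = fovRadiusFrac,
      backgroundLevel = backgroundLevel, vesselContrast = vesselContrast,
      noiseSd = noiseSd, illuminationGradient = illuminationGradient,
      seed = as.integer(seed))
}

#' @rdname AugmentConfig-class
#' @param maxRotationDeg,shiftFrac,maxZoomFrac,hflip,seed see slots.
#' @return An [AugmentConfig-class] object.
#' @export
augmentConfig <- function(maxRotationDeg = 15, shiftFrac = 0.10,
                          maxZoomFrac = 0.20, hflip = TRUE, seed = 42L) {
  new("AugmentConfig", maxRotationDeg = maxRotationDeg, shiftFrac = shiftFrac,
      maxZoomFrac = maxZoomFrac, hflip = isTRUE(hflip), seed = as.integer(seed))
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "FundusSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("FundusSample '%s' (%s): %d x %d, vessel fraction %.3f\n",
              object@id, object@source, d[1], d[2], mean(object@mask)))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d test samples\n",
              length(object@train), length(object@test)))
})

setMethod("show", "SegmentationModel", function(object) {
  s <- object@spec
  cat(sprintf("SegmentationModel '%s': input %d x %d, base width %d, %s parameters\n",
              s@name, s@inputSize[1], s@inputSize[2], s@baseChannels,
              format(parameterCount(object), big.mark = ",")))
})

setMethod("show", "MetaModel", function(object) {
  cat(sprintf("MetaModel: %d stacked inputs, %d hidden filters, %d parameters\n",
              object@kInputs, object@hiddenFilters,
              sum(vapply(object@module$params, function(p) length(p$value), 0))))
})

setMethod("show", "StackedPredictions", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("StackedPredictions: %d x %d x %d [%s]\n", d[1], d[2], d[3],
              paste(object@modelOrder, collapse = ", ")))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    "MetricReport (threshold %.2f, %d pixels)\n  Loss %.4f  Acc %.4f  SN %.4f  SP %.4f  AUC %s  F1 %.4f\n",
    object@threshold, object@nPixels, object@loss, object@acc, object@sn,
    object@sp, ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc)),
    object@f1))
  if (length(object@flags))
    cat("  0/0 cases defined as 0:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: %d epochs, best val loss %.4f at epoch %d\n",
              nrow(object@history), object@bestValLoss, object@bestEpoch))
})

## ---- small accessors ------------------------------------------------------

#' Accessors for sample and model objects
#'
#' @param x a [FundusSample-class], [SegmentationModel-class] or
#'   [StackedPredictions-class].
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
sampleId <- function(x) x@id

#' @rdname accessors
#' @export
sampleImage <- function(x) x@image

#' @rdname accessors
#' @export
sampleMask <- function(x) x@mask

#' @rdname accessors
#' @export
modelOrder <- function(x) x@modelOrder

#' @rdname accessors
#' @export
modelSpec <- function(x) x@spec

#' Number of trainable parameters
#' @param model a [SegmentationModel-class] or [MetaModel-class].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@module$params, function(p) length(p$value), numeric(1)))
}

#' Metric report as a one-row data.frame (report-table schema)
#'
#' @param x a [MetricReport-class].
#' @param row.names,optional,... ignored, present for the generic.
#' @return data.frame with columns Loss, Acc, SN, SP, AUC, F1.
#' @export
as.data.frame.MetricReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(Loss = x@loss, Acc = x@acc, SN = x@sn, SP = x@sp,
             AUC = x@auc, F1 = x@f1)
}
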