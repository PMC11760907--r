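## Stacking ensemble: channel-concatenate the base-model probability maps
## Z(x), train the small convolutional meta-model g on pixel-wise binary
## cross-entropy with the bases frozen, predict P_final(x) = g(Z(x)), and
## run subset ablations.

#' Canonical base-model order
#'
#' The fixed channel order used for stacking; recorded in every meta-model
#' checkpoint so channel semantics survive reload.
#' @return character vector of the four architecture names.
#' @export
canonicalModelOrder <- function() {
  c("unet", "resnet50_seg", "ctu_net", "unet_resnet_backbone")
}

#' Stack base-model probability maps into a feature tensor
#'
#' Channel-wise concatenation of K probability maps in the given order; the
#' values are untouched, and the order is part of the result's identity.
#'
#' @param maps named (or ordered) list of at least two H x W probability
#'   matrices with identical shapes.
#' @return A [StackedPredictions-class].
#' @export
stackPredictions <- function(maps) {
  if (length(maps) < 2L) stop("argument error: need at least 2 probability maps")
  d0 <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d0))
    stop("dimension mismatch: probability maps differ in shape")
  nm <- names(maps)
  if (is.null(nm)) nm <- paste0("model_", seq_along(maps))
  tensor <- array(unlist(maps, use.names = FALSE), c(d0, length(maps)))
  new("StackedPredictions", tensor = tensor, modelOrder = nm)
}

#' Build the convolutional meta-model
#'
#' Architecture: a 3x3 convolution with `hiddenFilters` filters (same
#' padding, ReLU, no bias term — the following layer's bias captures any
#' offset) over the K stacked base predictions, then a 1x1 convolution with
#' a single filter, bias and sigmoid.  At K = 4 and 64 hidden filters this
#' is 3*3*4*64 hidden weights plus (64 + 1) output parameters = 2369.
#'
#' @param kInputs number of stacked base models (>= 2).
#' @param hiddenFilters width of the 3x3 layer.
#' @param seed initialization seed.
#' @return A [MetaModel-class].
#' @export
buildMetaModel <- function(kInputs, hiddenFilters = 64L, seed = 42L) {
  if (kInputs < 2L) stop("argument error: kInputs must be >= 2")
  mod <- vsModule()
  withr::with_seed(seed, {
    c1 <- layerConv(mod, "meta.c1", 3L, as.integer(kInputs),
                    as.integer(hiddenFilters), bias = FALSE)
    c2 <- layerConv(mod, "meta.c2", 1L, as.integer(hiddenFilters), 1L,
                    act = "sigmoid")
  })
  mod$forward <- function(x) c2(c1(x))
  new("MetaModel", kInputs = as.integer(kInputs),
      hiddenFilters = as.integer(hiddenFilters), module = mod)
}

#' Predict with a meta-model on a stacked tensor
#' @param object a [MetaModel-class].
#' @param batch H x W x K stacked predictions (or H x W x K x B batch).
#' @param ... unused.
#' @return H x W probability matrix (or H x W x B array).
#' @export
setMethod("predict", "MetaModel", function(object, batch, ...) {
  if (is(batch, "StackedPredictions")) batch <- batch@tensor
  d <- dim(batch)
  if (d[3] != object@kInputs)
    stop(sprintf("configuration error: meta-model expects %d channels, got %d",
                 object@kInputs, d[3]))
  single <- length(d) == 3L
  if (single) dim(batch) <- c(d, 1L)
  old <- vsSetTraining(FALSE)
  on.exit(vsSetTraining(old))
  out <- object@module$forward(vsNode(batch))$value
  if (single) matrix(out, d[1], d[2]) else array(out, c(d[1], d[2], dim(batch)[4]))
})

## base predictions for a list of samples, one [H, W, K] per sample
basePredictionTensors <- function(baseModels, samples) {
  maps <- lapply(baseModels, function(m)
    lapply(samples, function(s) predict(m, s@image)))
  lapply(seq_along(samples), function(i)
    stackPredictions(lapply(maps, `[[`, i))@tensor)
}

#' Train the stacking meta-model on frozen base models
#'
#' Base predictions are computed once in inference mode (so the bases are
#' bit-identical before and after), stacked in the order of `baseModels`,
#' and only the meta-model's parameters are updated to minimize pixel-wise
#' binary cross-entropy against the ground-truth masks.  Checkpointing
#' follows the same first-best-validation-loss rule as base training.
#'
#' @param baseModels named list of trained [SegmentationModel-class] objects
#'   sharing one input size.
#' @param split a [DatasetSplit-class].
#' @param cfg a [TrainConfig-class]; augmentation is ignored here (the meta
#'   model consumes fixed base predictions).
#' @param meta optionally a pre-built [MetaModel-class]; default builds one
#'   with `seed = cfg@seed`.
#' @param verbose print per-epoch metric lines.
#' @return list with `meta` (best checkpoint) and `history`.
#' @export
trainMetaModel <- function(baseModels, split, cfg, meta = NULL, verbose = FALSE) {
  if (length(baseModels) < 2L) stop("argument error: need at least 2 base models")
  sizes <- vapply(baseModels, function(m) paste(m@spec@inputSize, collapse = "x"),
                  character(1))
  if (length(unique(sizes)) != 1L)
    stop("configuration error: base models must share one input size")
  if (length(split@train) == 0L) stop("argument error: empty training set")
  K <- length(baseModels)
  if (is.null(meta)) meta <- buildMetaModel(K, seed = cfg@seed)
  if (meta@kInputs != K)
    stop("configuration error: meta-model input count does not match the bases")
  ztr <- basePredictionTensors(baseModels, split@train)
  zte <- basePredictionTensors(baseModels, split@test)
  runTrainingLoop(
    mod = meta@module, cfg = cfg,
    train_inputs = ztr, train_masks = lapply(split@train, sampleMask),
    val_inputs = zte, val_masks = lapply(split@test, sampleMask),
    n_channels = K, augment = NULL, verbose = verbose)
  invisible(list(meta = meta, history = meta@module$last_history))
}

#' Ensemble inference: P_final(x) = g(Z(x))
#'
#' @param baseModels list of [SegmentationModel-class] objects in the
#'   stacking order the meta-model was trained with.
#' @param meta the trained [MetaModel-class].
#' @param image H x W x 3 input image.
#' @return H x W probability matrix.
#' @export
predictEnsemble <- function(baseModels, meta, image) {
  if (length(baseModels) != meta@kInputs)
    stop(sprintf("configuration error: meta-model expects %d base models, got %d",
                 meta@kInputs, length(baseModels)))
  z <- stackPredictions(lapply(baseModels, function(m) predict(m, image)))
  predict(meta, z)
}

#' The ten reference ablation subsets
#'
#' Five two-model, four three-model and the single four-model combination
#' over the canonical architectures.
#' @return list of character vectors of model names.
#' @export
defaultAblationSubsets <- function() {
  list(
    c("unet", "resnet50_seg"),
    c("resnet50_seg", "ctu_net"),
    c("resnet50_seg", "unet_resnet_backbone"),
    c("unet", "ctu_net"),
    c("unet", "unet_resnet_backbone"),
    c("resnet50_seg", "unet", "ctu_net"),
    c("resnet50_seg", "unet", "unet_resnet_backbone"),
    c("resnet50_seg", "ctu_net", "unet_resnet_backbone"),
    c("unet", "ctu_net", "unet_resnet_backbone"),
    c("unet", "resnet50_seg", "ctu_net", "unet_resnet_backbone"))
}

#' Ablation over base-model subsets
#'
#' Trains one meta-model per subset (fresh init, seeded identically from
#' `cfg@seed`, so duplicate subsets give identical rows), evaluates it on
#' the test split, and returns one report row per subset in the
#' Loss/Acc/SN/SP/AUC/F1 schema.
#'
#' @param baseModels named list of trained [SegmentationModel-class] objects.
#' @param split a [DatasetSplit-class].
#' @param cfg a [TrainConfig-class] for meta training.
#' @param subsets list of name vectors (size >= 2, subsets of
#'   `names(baseModels)`); default the ten reference combinations.
#' @param threshold evaluation threshold.
#' @param aucMaxPixels optional AUC pixel subsample.
#' @return data.frame, one row per subset.
#' @export
runAblation <- function(baseModels, split, cfg,
                        subsets = defaultAblationSubsets(), threshold = 0.5,
                        aucMaxPixels = NULL) {
  nms <- names(baseModels)
  for (ss in subsets) {
    if (length(ss) < 2L) stop("argument error: subsets must have size >= 2")
    bad <- setdiff(ss, nms)
    if (length(bad)) stop("argument error: unknown model name(s): ",
                          paste(bad, collapse = ", "))
  }
  reports <- lapply(subsets, function(ss) {
    fit <- trainMetaModel(baseModels[ss], split, cfg)
    maps <- lapply(split@test, function(s)
      predictEnsemble(baseModels[ss], fit$meta, s@image))
    evaluateModel(maps, split@test, threshold = threshold,
                  aucMaxPixels = aucMaxPixels)
  })
  names(reports) <- vapply(subsets, paste, character(1), collapse = " + ")
  metricTable(reports)
}
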