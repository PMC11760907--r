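## End-to-end experiment runner: YAML config -> trained base models, stacked
## meta-model, report tables, histories, predicted masks and a manifest.

displayName <- function(name) {
  c(unet = "U-Net", resnet50_seg = "ResNet50",
    unet_resnet_backbone = "U-Net-ResNet50-backbone",
    ctu_net = "CTU-Net")[[name]]
}

#' Validate an experiment configuration
#'
#' @param cfg configuration list (parsed YAML).
#' @return the configuration with defaults filled in; raises a schema error
#'   listing all offending keys otherwise.
#' @export
validateExperimentConfig <- function(cfg) {
  problems <- character()
  need <- function(cond, key) if (!cond) problems <<- c(problems, key)
  data <- cfg$data
  need(!is.null(data), "data")
  if (!is.null(data)) {
    need(identical(data$source, "synthetic") || identical(data$source, "real"),
         "data.source")
    if (identical(data$source, "synthetic")) {
      need(is.numeric(data$n) && data$n >= 2, "data.n")
    } else if (identical(data$source, "real")) {
      need(is.character(unlist(data$images_dir)), "data.images_dir")
      need(is.character(unlist(data$masks_dir)), "data.masks_dir")
    }
    need(is.numeric(data$n_train) && data$n_train >= 1, "data.n_train")
  }
  arch <- cfg$architectures
  if (!is.null(arch$base_channels))
    need(is.numeric(arch$base_channels) && arch$base_channels >= 1,
         "architectures.base_channels")
  tr <- cfg$train
  if (!is.null(tr)) {
    if (!is.null(tr$learning_rate)) need(tr$learning_rate > 0, "train.learning_rate")
    if (!is.null(tr$epochs)) need(tr$epochs >= 0, "train.epochs")
    if (!is.null(tr$batch_size)) need(tr$batch_size >= 1, "train.batch_size")
  }
  if (length(problems))
    stop("schema error in experiment config; offending keys: ",
         paste(problems, collapse = ", "))
  cfg$data$image_size <- cfg$data$image_size %||% 256L
  cfg$data$seed <- cfg$data$seed %||% 42L
  cfg$architectures <- arch %||% list()
  cfg$architectures$base_channels <- cfg$architectures$base_channels %||% 64L
  cfg$architectures$depth <- cfg$architectures$depth %||% 4L
  cfg$architectures$seed <- cfg$architectures$seed %||% cfg$data$seed
  cfg$train <- tr %||% list()
  cfg$train$learning_rate <- cfg$train$learning_rate %||% 0.01
  cfg$train$epochs <- cfg$train$epochs %||% 500L
  cfg$train$batch_size <- cfg$train$batch_size %||% 32L
  cfg$train$seed <- cfg$train$seed %||% cfg$data$seed
  cfg$ensemble <- cfg$ensemble %||% list()
  cfg$ensemble$enabled <- cfg$ensemble$enabled %||% TRUE
  cfg$ensemble$ablation <- cfg$ensemble$ablation %||% FALSE
  cfg$threshold <- cfg$threshold %||% 0.5
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full experiment from a YAML config
#'
#' Loads or generates the dataset, trains the four base architectures under
#' the configured protocol, trains the stacking meta-model on the frozen
#' bases, evaluates everything on the test split, and writes to `outDir`:
#' per-model training histories (CSV), a report CSV in the
#' Loss/ACC/SN/SP/AUC/F1 schema with a Meta-model row, the optional ablation
#' CSV, predicted test masks (PNG), model checkpoints, a split manifest and
#' a JSON manifest capturing config, seeds and package version.  Re-running
#' with an identical config reproduces the report byte for byte on one
#' device.
#'
#' @param configPath path to the YAML experiment config.
#' @param outDir output directory (created; defaults to `experiment_<stem>`
#'   next to the config).
#' @param verbose print per-epoch metric lines.
#' @return `outDir`, invisibly.
#' @export
runExperiment <- function(configPath, outDir = NULL, verbose = FALSE) {
  cfg <- validateExperimentConfig(yaml::read_yaml(configPath))
  if (is.null(outDir))
    outDir <- file.path(dirname(configPath),
                        paste0("experiment_",
                               tools::file_path_sans_ext(basename(configPath))))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  data <- cfg$data
  sz <- rep_len(as.integer(data$image_size), 2L)
  samples <- if (identical(data$source, "synthetic")) {
    # optional data$tree / data$render blocks override generator defaults
    treeCfg <- do.call(vesselTreeConfig,
                       c(list(imageSize = sz), data$tree %||% list()))
    renderCfg <- do.call(fundusRenderConfig, data$render %||% list())
    makeSyntheticDataset(as.integer(data$n), treeCfg = treeCfg,
                         renderCfg = renderCfg, seed = as.integer(data$seed))
  } else {
    # images_dir/masks_dir may be parallel lists: sources are pooled, so one
    # experiment can train on several datasets at once (default: a single one)
    ids <- unlist(data$images_dir)
    mds <- unlist(data$masks_dir)
    if (length(ids) != length(mds))
      stop("schema error in experiment config; offending keys: ",
           "data.images_dir, data.masks_dir (lengths differ)")
    do.call(c, lapply(seq_along(ids), function(i) {
      ss <- loadDataset(ids[i], mds[i], targetSize = sz)
      if (length(ids) > 1L) # keep pooled ids collision-free
        ss <- lapply(ss, function(s) { s@id <- sprintf("src%d_%s", i, s@id); s })
      ss
    }))
  }
  split <- splitDataset(samples, as.integer(data$n_train),
                        seed = as.integer(data$seed),
                        shuffle = isTRUE(data$shuffle))
  writeSplitManifest(split, file.path(outDir, "split.csv"))

  aug <- cfg$train$augment
  augCfg <- if (isTRUE(aug)) augmentConfig(seed = as.integer(cfg$train$seed))
    else if (is.list(aug)) augmentConfig(
      maxRotationDeg = aug$max_rotation_deg %||% 15,
      shiftFrac = aug$shift_frac %||% 0.10,
      maxZoomFrac = aug$max_zoom_frac %||% 0.20,
      hflip = aug$hflip %||% TRUE, seed = as.integer(cfg$train$seed))
    else NULL
  tc <- trainConfig(learningRate = cfg$train$learning_rate,
                    epochs = cfg$train$epochs,
                    batchSize = cfg$train$batch_size,
                    seed = as.integer(cfg$train$seed), augment = augCfg)

  arch <- cfg$architectures
  names_ <- canonicalModelOrder()
  models <- list()
  reports <- list()
  for (nm in names_) {
    spec <- architectureSpec(nm, inputSize = sz,
                             baseChannels = as.integer(arch$base_channels),
                             depth = as.integer(arch$depth),
                             seed = as.integer(arch$seed))
    model <- buildModel(spec)
    if (verbose) message("training ", displayName(nm))
    fit <- trainSegmentationModel(model, split, tc, verbose = verbose)
    utils::write.csv(fit$history@history,
                     file.path(outDir, paste0("history_", nm, ".csv")),
                     row.names = FALSE)
    saveCheckpoint(model, file.path(outDir, paste0("checkpoint_", nm, ".rds")))
    models[[nm]] <- model
    reports[[displayName(nm)]] <-
      evaluateModel(model, split@test, threshold = cfg$threshold)
  }

  if (isTRUE(cfg$ensemble$enabled)) {
    if (verbose) message("training Meta-model")
    fit <- trainMetaModel(models, split, tc, verbose = verbose)
    utils::write.csv(fit$history@history,
                     file.path(outDir, "history_meta.csv"), row.names = FALSE)
    saveCheckpoint(fit$meta, file.path(outDir, "checkpoint_meta.rds"))
    maps <- lapply(split@test, function(s)
      predictEnsemble(models, fit$meta, s@image))
    reports[["Meta-model"]] <- evaluateModel(maps, split@test,
                                             threshold = cfg$threshold)
    maskDir <- file.path(outDir, "predicted_masks")
    dir.create(maskDir, showWarnings = FALSE)
    for (i in seq_along(split@test)) {
      writeProbabilityMap(maps[[i]],
                          file.path(maskDir, paste0(split@test[[i]]@id, ".png")),
                          threshold = cfg$threshold)
    }
  }

  report <- metricTable(reports)
  names(report)[names(report) == "Acc"] <- "ACC"
  utils::write.csv(report, file.path(outDir, "report.csv"), row.names = FALSE)

  if (isTRUE(cfg$ensemble$ablation)) {
    abl <- runAblation(models, split, tc)
    utils::write.csv(abl, file.path(outDir, "ablation.csv"), row.names = FALSE)
  }

  jsonlite::write_json(
    list(config = cfg,
         package_version = as.character(utils::packageVersion("vesselStack")),
         n_train = length(split@train), n_test = length(split@test)),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
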