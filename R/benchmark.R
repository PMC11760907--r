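## Desk-scale synthetic benchmark used to measure the stacking benefit:
## trains the four reduced-width architectures and the meta-model on one
## seeded synthetic dataset and reports test-set metrics for all five.

#' Synthetic ensemble benchmark
#'
#' Generates a seeded synthetic dataset, trains all four base architectures
#' at reduced width under one protocol, trains the stacking meta-model on
#' the frozen bases, and evaluates everything on the held-out test images.
#' This is the package's reference experiment for the ensemble-benefit
#' property (the four-model meta F1 should not fall meaningfully below the
#' best base F1).
#'
#' @param seed master seed (data, initialization and training draws all
#'   derive from it).
#' @param n,nTrain dataset size and training-set size.
#' @param imageSize square image side; must suit all architectures
#'   (divisible by 32).
#' @param baseChannels reduced width for the base networks.
#' @param epochs,batchSize,learningRate training protocol for bases and meta.
#' @param threshold evaluation threshold.
#' @param verbose print per-epoch metric lines.
#' @return list with `reports` (named [MetricReport-class] list including
#'   `"Meta-model"`), `baseF1` (named numeric), `metaF1`, and `table`
#'   (the report data.frame).
#' @export
syntheticEnsembleBenchmark <- function(seed, n = 50L, nTrain = 40L,
                                       imageSize = 64L, baseChannels = 2L,
                                       epochs = 30L, batchSize = 4L,
                                       learningRate = 2e-3, threshold = 0.5,
                                       verbose = FALSE) {
  samples <- makeSyntheticDataset(
    n, vesselTreeConfig(imageSize = c(imageSize, imageSize)),
    fundusRenderConfig(), seed = seed)
  split <- splitDataset(samples, nTrain)
  tc <- trainConfig(learningRate = learningRate, epochs = epochs,
                    batchSize = batchSize, seed = seed)
  models <- list()
  reports <- list()
  for (nm in canonicalModelOrder()) {
    model <- buildModel(architectureSpec(
      nm, inputSize = c(imageSize, imageSize),
      baseChannels = as.integer(baseChannels), seed = seed))
    trainSegmentationModel(model, split, tc, verbose = verbose)
    models[[nm]] <- model
    reports[[displayName(nm)]] <- evaluateModel(model, split@test,
                                                threshold = threshold)
  }
  fit <- trainMetaModel(models, split, tc, verbose = verbose)
  maps <- lapply(split@test, function(s) predictEnsemble(models, fit$meta, s@image))
  reports[["Meta-model"]] <- evaluateModel(maps, split@test, threshold = threshold)
  baseF1 <- vapply(reports[seq_len(4L)], function(r) r@f1, numeric(1))
  list(reports = reports, baseF1 = baseF1,
       metaF1 = reports[["Meta-model"]]@f1, table = metricTable(reports))
}
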