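# Stacking: losslessness of Z(x), the meta-model head, frozen-base training,
# ensemble inference and the ablation harness.

test_that("stacking is channel-lossless and order-preserving", {
  set.seed(60)
  maps <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  names(maps) <- canonicalModelOrder()
  z <- stackPredictions(maps)
  expect_identical(dim(z@tensor), c(16L, 16L, 4L))
  expect_identical(z@modelOrder, canonicalModelOrder())
  for (k in 1:4) expect_identical(z@tensor[, , k], maps[[k]])
  # permuting the inputs permutes channels identically
  perm <- c(3, 1, 4, 2)
  z2 <- stackPredictions(maps[perm])
  expect_identical(z2@modelOrder, canonicalModelOrder()[perm])
  for (k in 1:4) expect_identical(z2@tensor[, , k], maps[[perm[k]]])
  expect_error(stackPredictions(maps[1]), "argument error")
  expect_error(stackPredictions(list(maps[[1]], matrix(0.5, 8, 8))),
               "dimension mismatch")
})

test_that("the meta-model head has the stated layer shapes and size", {
  meta <- buildMetaModel(4)
  # (3*3*4*64 + 64) + (1*1*64*1 + 1)
  expect_identical(parameterCount(meta), 2369)
  expect_identical(dim(meta@module$params[["meta.c1.w"]]$value), c(3L, 3L, 4L, 64L))
  expect_identical(dim(meta@module$params[["meta.c2.w"]]$value), c(1L, 1L, 64L, 1L))
  # forward contract on a stacked batch
  zb <- array(runif(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  p <- predict(meta, zb)
  expect_identical(dim(p), c(16L, 16L, 3L))
  expect_true(all(p > 0 & p < 1))
  # two-model metas build (the pairwise ablation rows)
  expect_identical(buildMetaModel(2)@kInputs, 2L)
  expect_error(buildMetaModel(1), "argument error")
})

test_that("meta training leaves base parameters bit-identical", {
  samples <- tinySamples(6, size = 32, seed = 61)
  split <- splitDataset(samples, 4)
  bases <- list(
    unet = buildUnet(tinySpec("unet", 32L, 2L, seed = 1L)),
    ctu_net = buildCtuNet(tinySpec("ctu_net", 32L, 2L, seed = 2L)))
  snaps <- lapply(bases, function(m) vesselStack:::paramSnapshot(m@module$params))
  cfg <- trainConfig(learningRate = 1e-2, epochs = 3, batchSize = 2, seed = 5L)
  fit <- trainMetaModel(bases, split, cfg)
  for (nm in names(bases)) {
    expect_identical(vesselStack:::paramSnapshot(bases[[nm]]@module$params),
                     snaps[[nm]])
  }
  expect_s4_class(fit$meta, "MetaModel")
  expect_identical(nrow(fit$history@history), 3L)
})

test_that("zero-epoch meta training is a no-op with empty history", {
  samples <- tinySamples(3, size = 32, seed = 62)
  split <- splitDataset(samples, 2)
  bases <- list(
    unet = buildUnet(tinySpec("unet", 32L, 2L, seed = 1L)),
    ctu_net = buildCtuNet(tinySpec("ctu_net", 32L, 2L, seed = 2L)))
  meta <- buildMetaModel(2, seed = 3L)
  before <- vesselStack:::paramSnapshot(meta@module$params)
  fit <- trainMetaModel(bases, split, trainConfig(epochs = 0, seed = 5L),
                        meta = meta)
  expect_identical(vesselStack:::paramSnapshot(fit$meta@module$params), before)
  expect_identical(nrow(fit$history@history), 0L)
})

test_that("a meta fed perfect base predictions converges to near-zero loss", {
  # two 'bases' that already output the truth: stacking the masks themselves;
  # an averaging 1x1 head reproduces the truth, so training must reach <= 0.05
  samples <- tinySamples(4, size = 32, seed = 63)
  z <- lapply(samples, function(s) array(rep(s@mask, 2), c(32, 32, 2)))
  y <- lapply(samples, sampleMask)
  meta <- buildMetaModel(2, seed = 4L)
  hist <- vesselStack:::runTrainingLoop(
    mod = meta@module, cfg = trainConfig(learningRate = 0.05, epochs = 50,
                                         batchSize = 1, seed = 6L),
    train_inputs = z, train_masks = y, val_inputs = z, val_masks = y,
    n_channels = 2L)
  expect_lte(tail(hist@history$train_loss, 1), 0.05)
})

test_that("ensemble inference is deterministic and monotone-equivalent to a pass-through", {
  samples <- tinySamples(2, size = 32, seed = 64)
  bases <- list(
    unet = buildUnet(tinySpec("unet", 32L, 2L, seed = 1L)),
    ctu_net = buildCtuNet(tinySpec("ctu_net", 32L, 2L, seed = 2L)))
  meta <- buildMetaModel(2, hiddenFilters = 4L, seed = 3L)
  img <- samples[[1]]@image
  p1 <- predictEnsemble(bases, meta, img)
  expect_identical(predictEnsemble(bases, meta, img), p1)
  expect_identical(dim(p1), c(32L, 32L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predictEnsemble(bases[1:1], meta, img), "configuration error")
  # hand-set the meta to pass channel 1 through: hidden filter 1 = centre tap
  # of channel 1 (ReLU-safe since probabilities are positive), output = that
  # filter; the result is a monotone transform of base 1, so AUC is unchanged
  for (p in meta@module$params) p$value <- p$value * 0
  w1 <- meta@module$params[["meta.c1.w"]]$value
  w1[2, 2, 1, 1] <- 3
  meta@module$params[["meta.c1.w"]]$value <- w1
  w2 <- meta@module$params[["meta.c2.w"]]$value
  w2[1, 1, 1, 1] <- 2
  meta@module$params[["meta.c2.w"]]$value <- w2
  base1 <- predict(bases$unet, img)
  pf <- predictEnsemble(bases, meta, img)
  truth <- samples[[1]]@mask
  expect_equal(rocAuc(pf, truth), rocAuc(base1, truth), tolerance = 1e-12)
  # and the map itself is sigmoid(2 * relu(3 * base1))
  expect_equal(pf, 1 / (1 + exp(-2 * pmax(3 * base1, 0))), tolerance = 1e-10)
})

test_that("the ablation harness emits the ten reference rows in schema", {
  subsets <- defaultAblationSubsets()
  expect_length(subsets, 10L)
  expect_identical(sum(lengths(subsets) == 2), 5L)
  expect_identical(sum(lengths(subsets) == 3), 4L)
  expect_identical(sum(lengths(subsets) == 4), 1L)
  samples <- tinySamples(6, size = 32, seed = 65)
  split <- splitDataset(samples, 4)
  bases <- sapply(canonicalModelOrder(), function(nm)
    buildModel(tinySpec(nm, 32L, 2L, seed = match(nm, canonicalModelOrder()))),
    simplify = FALSE)
  cfg <- trainConfig(learningRate = 1e-2, epochs = 2, batchSize = 2, seed = 5L)
  tab <- runAblation(bases, split, cfg)
  expect_identical(nrow(tab), 10L)
  expect_identical(names(tab),
                   c("Model", "Loss", "Acc", "SN", "SP", "AUC", "F1-Score"))
  expect_identical(tab$Model[10],
                   "unet + resnet50_seg + ctu_net + unet_resnet_backbone")
  # a duplicated subset reproduces its row exactly (same seed, fresh init)
  dup <- runAblation(bases, split, cfg,
                     subsets = list(c("unet", "ctu_net"), c("unet", "ctu_net")))
  expect_identical(dup[1, -1], dup[2, -1], ignore_attr = TRUE)
  expect_error(runAblation(bases, split, cfg, subsets = list(c("unet", "nope"))),
               "unknown model name")
  expect_error(runAblation(bases, split, cfg, subsets = list("unet")),
               "argument error")
})
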