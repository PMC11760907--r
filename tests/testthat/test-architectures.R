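# Shared forward contract of the four builders plus architecture-specific
# structure checks (parameter scaling, token counts, residual block table).

test_that("all four builders satisfy the shared forward contract", {
  set.seed(50)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  for (nm in allArchitectures()) {
    spec <- tinySpec(nm, size = 32L, base = 4L)
    m <- buildModel(spec)
    p <- predict(m, x)
    # spatial size preserved, batch dim preserved, values strictly in (0,1)
    expect_identical(dim(p), c(32L, 32L, 2L))
    expect_true(all(p > 0 & p < 1))
    # eval-mode determinism
    expect_identical(predict(m, x), p)
    # seeded-init determinism: a fresh build reproduces the same outputs
    expect_identical(predict(buildModel(spec), x), p)
    # single-image input yields a matrix
    p1 <- predict(m, x[, , , 1])
    expect_identical(dim(p1), c(32L, 32L))
    expect_equal(p1, p[, , 1], tolerance = 1e-12)
    # wrong spatial size is a dimension error
    expect_error(predict(m, array(0.5, c(16, 16, 3))), "dimension mismatch")
  }
})

test_that("doubling baseChannels roughly quadruples U-Net parameters", {
  n8 <- parameterCount(buildUnet(tinySpec("unet", size = 64L, base = 8L)))
  n16 <- parameterCount(buildUnet(tinySpec("unet", size = 64L, base = 16L)))
  expect_gte(n16 / n8, 3.5)
  expect_lte(n16 / n8, 4.5)
})

test_that("input sizes must suit the downsampling schedule", {
  expect_error(architectureSpec("unet", inputSize = c(60, 60), baseChannels = 8),
               "divisible")
  expect_error(architectureSpec("resnet50_seg", inputSize = c(48, 48),
                                baseChannels = 8), "divisible by 32")
  expect_error(architectureSpec("ctu_net", inputSize = c(64, 64),
                                baseChannels = 8,
                                transformer = list(n_heads = 5L)),
               "n_heads")
  # 256 x 256 (the reference resolution) is accepted by every builder
  for (nm in allArchitectures()) {
    expect_s4_class(architectureSpec(nm, inputSize = c(256, 256)),
                    "ArchitectureSpec")
  }
})

test_that("the transformer bottleneck tokenizes one position per pixel", {
  spec <- tinySpec("ctu_net", size = 64L, base = 8L)
  m <- buildCtuNet(spec)
  pos <- m@module$params[["bott.pos"]]$value
  # 64 / 2^4 = 4 per side -> 16 tokens; embedding dim 2^4 * 8 = 128
  expect_identical(dim(pos), c(16L, 128L))
})

test_that("the ResNet encoder has the canonical 3/4/6/3 block table", {
  m <- buildResnet50Seg(tinySpec("resnet50_seg", size = 32L, base = 2L))
  nm <- names(m@module$params)
  blocks <- unique(sub("\\.(c[123]|proj)\\..*$", "",
                       grep("^enc\\.s[0-9]", nm, value = TRUE)))
  expect_length(blocks, 16L)
  counts <- table(sub("^enc\\.(s[1-4])\\..*$", "\\1", blocks))
  expect_identical(as.integer(counts[c("s1", "s2", "s3", "s4")]), c(3L, 4L, 6L, 3L))
  # stem is a 7x7 conv over RGB
  expect_identical(dim(m@module$params[["enc.stem.w"]]$value)[1:3], c(7L, 7L, 3L))
})

test_that("the backbone model taps four skip connections", {
  m <- buildUnetResnetBackbone(tinySpec("unet_resnet_backbone", size = 32L,
                                        base = 2L))
  # decoder levels 1..4 concatenate a tap; level 5 upsamples without one:
  # visible in the first-conv input widths (out_ch + skip_ch vs out_ch)
  nm <- names(m@module$params)
  dec_in <- vapply(sprintf("ddec%d.c1.w", 1:5),
                   function(k) dim(m@module$params[[k]]$value)[3], integer(1))
  out_ch <- c(8L, 4L, 2L, 1L, 1L) * 2L
  skip_ch <- c(16L, 8L, 4L, 1L, 0L) * 2L # stride-16..2 taps, none at full res
  expect_identical(unname(dec_in), out_ch + skip_ch)
})

test_that("pretrained-backbone builds demand a weight source", {
  sp <- architectureSpec("resnet50_seg", inputSize = c(32, 32),
                         baseChannels = 2L, pretrainedBackbone = TRUE)
  expect_error(buildResnet50Seg(sp), "weights")
})

test_that("freezing the encoder stops its updates but not the decoder's", {
  m <- buildUnetResnetBackbone(tinySpec("unet_resnet_backbone", size = 32L,
                                        base = 2L, seed = 3L))
  freezeParameters(m, "enc.")
  enc_before <- vesselStack:::paramSnapshot(
    m@module$params[startsWith(names(m@module$params), "enc.")])
  dec_names <- grep("^ddec1", names(m@module$params), value = TRUE)
  dec_before <- vesselStack:::paramSnapshot(m@module$params[dec_names])
  b <- samplesToBatch(tinySamples(2, 32, seed = 51))
  overfitBatch(m, b$x, b$y, steps = 2)
  enc_after <- vesselStack:::paramSnapshot(
    m@module$params[startsWith(names(m@module$params), "enc.")])
  expect_identical(enc_after, enc_before)
  dec_after <- vesselStack:::paramSnapshot(m@module$params[dec_names])
  expect_false(identical(dec_after, dec_before))
})

test_that("removing skip connections degrades convergence on a tiny task", {
  b <- samplesToBatch(tinySamples(2, 32, seed = 52))
  wins <- 0L
  for (seed in 1:5) {
    with_skips <- buildUnet(tinySpec("unet", size = 32L, base = 4L, seed = seed))
    without <- buildUnet(tinySpec("unet", size = 32L, base = 4L, seed = seed))
    without@module$use_skips <- FALSE
    lw <- tail(overfitBatch(with_skips, b$x, b$y, steps = 80), 1)
    ln <- tail(overfitBatch(without, b$x, b$y, steps = 80), 1)
    if (ln > lw) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("checkpoints reload to the exact same predictor", {
  m <- buildCtuNet(tinySpec("ctu_net", size = 32L, base = 4L, seed = 9L))
  b <- samplesToBatch(tinySamples(2, 32, seed = 53))
  overfitBatch(m, b$x, b$y, steps = 3) # move off the init, populate BN state
  f <- file.path(withr::local_tempdir(), "ck.rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(predict(m2, b$x[, , , 1]), predict(m, b$x[, , , 1]))
})
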