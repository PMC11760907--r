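# Synthetic vessel trees, fundus rendering and geometric augmentation.

test_that("vessel mask generation is seeded-deterministic and validated", {
  cfg <- vesselTreeConfig(imageSize = c(48, 48), seed = 5L)
  m1 <- generateVesselMask(cfg)
  m2 <- generateVesselMask(cfg)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0, 1)))
  expect_error(vesselTreeConfig(imageSize = c(48, 48), nRoots = 0), "nRoots")
  expect_error(vesselTreeConfig(imageSize = c(48, 48), rootWidth = 2,
                                minWidth = 5), "minWidth")
})

test_that("a single unbranched stroke covers about stepLen x width pixels", {
  # polygon-fill oracle: point-in-rectangle via half-plane tests on the
  # stroke's four corners (independent of the projection-based rasterizer)
  polyCount <- function(p0, p1, w, H, W) {
    v <- p1 - p0
    len <- sqrt(sum(v^2))
    u <- v / len
    nrm <- c(-u[2], u[1]) * (w / 2)
    corners <- rbind(p0 + nrm, p1 + nrm, p1 - nrm, p0 - nrm)
    inside <- function(x, y) {
      s <- sapply(1:4, function(k) {
        a <- corners[k, ]; b <- corners[(k %% 4) + 1, ]
        (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      })
      all(s <= 1e-9) || all(s >= -1e-9)
    }
    n <- 0
    for (x in 1:W) for (y in 1:H) if (inside(x, y)) n <- n + 1
    n
  }
  set.seed(33)
  for (i in 1:4) {
    p0 <- c(20, 20) + runif(2, -3, 3)
    ang <- runif(1, 0, 2 * pi)
    L <- 10; w <- 4
    p1 <- p0 + L * c(cos(ang), sin(ang))
    m <- vesselStack:::strokeRect(matrix(0, 40, 40), p0, p1, w)
    expect_equal(sum(m), polyCount(p0, p1, w, 40, 40), tolerance = 2 / max(1, sum(m)))
  }
  # whole-generator version of the same bound: one root, one step, no branches
  for (seed in c(2L, 9L, 17L)) {
    cfg <- vesselTreeConfig(imageSize = c(64, 64), nRoots = 1, maxDepth = 1,
                            branchProb = 0, stepLen = 10, angleJitterSd = 0,
                            rootWidth = 4, seed = seed)
    n <- sum(generateVesselMask(cfg))
    expect_gte(n, 10 * (4 - 1))
    expect_lte(n, 10 * (4 + 2))
  }
})

test_that("default vessel masks are sparse but non-empty", {
  for (seed in c(1L, 2L, 3L)) {
    for (size in c(64L, 128L)) {
      f <- mean(generateVesselMask(vesselTreeConfig(imageSize = c(size, size),
                                                    seed = seed)))
      expect_gt(f, 0)
      expect_lt(f, 0.35)
    }
  }
})

test_that("rendering follows the illumination model", {
  mask <- generateVesselMask(vesselTreeConfig(imageSize = c(48, 48), seed = 4L))
  # no vessels, no noise, no gradient: constant inside the FOV, black outside
  cfg0 <- fundusRenderConfig(noiseSd = 0, illuminationGradient = 0,
                             backgroundLevel = 0.6)
  img <- renderFundusImage(matrix(0, 48, 48), cfg0)
  red <- img[, , 1]
  ctr <- (48 + 1) / 2
  fov <- (matrix((1:48 - ctr)^2, 48, 48, byrow = TRUE) +
            matrix((1:48 - ctr)^2, 48, 48)) <= (0.95 * 24)^2
  expect_true(all(abs(red[fov] - 0.6) < 1e-12))
  expect_true(all(red[!fov] == 0))
  # zero contrast decouples the image from the mask
  imgA <- renderFundusImage(mask, fundusRenderConfig(vesselContrast = 0,
                                                     noiseSd = 0))
  imgB <- renderFundusImage(matrix(0, 48, 48),
                            fundusRenderConfig(vesselContrast = 0, noiseSd = 0))
  expect_identical(imgA, imgB)
  # with contrast, vessel pixels are darker than the non-vessel FOV
  img2 <- renderFundusImage(mask, fundusRenderConfig(noiseSd = 0))
  red2 <- img2[, , 1]
  expect_lt(mean(red2[mask == 1 & fov]), mean(red2[mask == 0 & fov]))
  # red channel dominates
  expect_true(all(img2[, , 1] >= img2[, , 2]))
  expect_true(all(img2[, , 2] >= img2[, , 3]))
})

test_that("augmentation defaults match the reference policy", {
  cfg <- augmentConfig()
  expect_equal(cfg@maxRotationDeg, 15)
  expect_equal(cfg@shiftFrac, 0.10)
  expect_equal(cfg@maxZoomFrac, 0.20)
  expect_true(cfg@hflip)
})

test_that("zeroed augmentation ranges give the identity transform", {
  s <- tinySamples(1, size = 24, seed = 41)[[1]]
  cfg <- augmentConfig(maxRotationDeg = 0, shiftFrac = 0, maxZoomFrac = 0,
                       hflip = FALSE)
  out <- augmentSample(s, cfg, drawSeed = 3L)
  expect_equal(out@image, s@image, tolerance = 1e-12)
  expect_identical(out@mask, s@mask)
})

test_that("a pure horizontal flip is a column reversal and an involution", {
  s <- tinySamples(1, size = 24, seed = 42)[[1]]
  cfg <- augmentConfig(maxRotationDeg = 0, shiftFrac = 0, maxZoomFrac = 0,
                       hflip = TRUE)
  # find a draw seed whose flip coin lands heads
  seed <- NULL
  for (cand in 1:30) {
    if (withr::with_seed(cand, {
      stats::runif(4) # rotation, tx, ty, zoom draws
      stats::runif(1) < 0.5
    })) { seed <- cand; break }
  }
  expect_false(is.null(seed))
  out <- augmentSample(s, cfg, drawSeed = seed)
  expect_equal(out@image, s@image[, ncol(s@mask):1, ], tolerance = 1e-12)
  expect_identical(out@mask, s@mask[, ncol(s@mask):1])
  back <- augmentSample(out, cfg, drawSeed = seed)
  expect_equal(back@image, s@image, tolerance = 1e-12)
  expect_identical(back@mask, s@mask)
})

test_that("any augmentation draw preserves mask binarity and image range", {
  s <- tinySamples(1, size = 24, seed = 43)[[1]]
  cfg <- augmentConfig()
  for (seed in 1:8) {
    out <- augmentSample(s, cfg, drawSeed = seed)
    expect_true(all(out@mask %in% c(0, 1)))
    expect_true(all(out@image >= 0 & out@image <= 1))
    expect_identical(dim(out@image), dim(s@image))
  }
})

test_that("image and mask stay geometrically consistent under augmentation", {
  # build a sample whose mask is exactly the image's darkest quartile;
  # after any draw, >= 90% of the warped mask's foreground must still fall
  # in the darkest quartile of the warped image (within the valid region)
  set.seed(44)
  H <- 48
  rr <- matrix(1:H, H, H)
  cc <- t(rr)
  mask <- (((rr - 16)^2 + (cc - 16)^2 <= 9^2) |
             ((rr - 33)^2 + (cc - 31)^2 <= 8^2)) * 1
  field <- matrix(runif(H * H, 0.6, 0.9), H, H)
  for (i in 1:6) field <- vesselStack:::blur3(field)
  img <- array(rep(field - 0.45 * mask, 3), c(H, H, 3))
  s <- fundusSample("gc", img, mask, "synthetic")
  cfg <- augmentConfig()
  for (seed in c(2L, 5L, 8L, 11L)) {
    out <- augmentSample(s, cfg, drawSeed = seed)
    valid <- augmentSample(fundusSample("v", img, matrix(1, H, H), "synthetic"),
                           cfg, drawSeed = seed)@mask == 1
    wimg <- out@image[, , 1]
    fg <- out@mask == 1 & valid
    qv <- quantile(wimg[valid], mean(out@mask[valid]))
    if (sum(fg) > 0) {
      expect_gte(mean(wimg[fg] <= qv + 1e-9), 0.9)
    }
  }
})

test_that("synthetic datasets are deterministic, well-formed and splittable", {
  expect_error(makeSyntheticDataset(0), "argument error")
  a <- makeSyntheticDataset(2, vesselTreeConfig(imageSize = c(32, 32)),
                            fundusRenderConfig(), seed = 9L)
  b <- makeSyntheticDataset(2, vesselTreeConfig(imageSize = c(32, 32)),
                            fundusRenderConfig(), seed = 9L)
  expect_identical(a[[1]]@image, b[[1]]@image)
  expect_identical(a[[2]]@mask, b[[2]]@mask)
  expect_identical(vapply(a, sampleId, ""), c("synth_0000", "synth_0001"))
  # a 20-sample set supports the 14/6 split convention end to end
  d <- makeSyntheticDataset(20, vesselTreeConfig(imageSize = c(32, 32)),
                            fundusRenderConfig(), seed = 10L)
  expect_length(d, 20)
  for (s in d) expect_true(validObject(s))
  sp <- splitDataset(d, 14)
  expect_length(sp@train, 14)
  expect_length(sp@test, 6)
})

test_that("generator calls leave the global RNG stream untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(generateVesselMask(vesselTreeConfig(imageSize = c(32, 32), seed = 1L)))
  invisible(makeSyntheticDataset(1, vesselTreeConfig(imageSize = c(32, 32)),
                                 fundusRenderConfig(), seed = 2L))
  invisible(augmentSample(tinySamples(1, 16)[[1]], augmentConfig(), drawSeed = 3L))
  expect_identical(.Random.seed, before)
})
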