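## Synthetic fundus generator: branching vessel trees with exact ground
## truth, fundus-style rendering (circular field of view, low contrast,
## noise), and the geometric augmentation policy.  Everything is driven by
## explicit seeds; no call leaves the global RNG state altered
## (withr::with_seed restores it).

#' Generate a branching vessel mask
#'
#' Draws a vessel tree by a recursive random walk.  Each root starts on the
#' field-of-view boundary heading inward; at every step the heading is
#' perturbed by `Normal(0, angleJitterSd)` and a rectangular stroke of the
#' current width and `stepLen` length is rasterized; with probability
#' `branchProb` a child branch spawns at 20-50 degrees to the parent with
#' width multiplied by `widthDecay`.  Walks terminate after `maxDepth`
#' steps, when the width falls below `minWidth`, or on leaving the image.
#'
#' @param cfg a [VesselTreeConfig-class].
#' @return H x W binary matrix (1 = vessel).
#' @export
generateVesselMask <- function(cfg) {
  stopifnot(is(cfg, "VesselTreeConfig"))
  validObject(cfg)
  H <- cfg@imageSize[1]; W <- cfg@imageSize[2]
  mask <- matrix(0, H, W)
  ctr <- c((W + 1) / 2, (H + 1) / 2)  # (x, y)
  radius <- 0.92 * min(H, W) / 2
  withr::with_seed(cfg@seed, {
    queue <- lapply(seq_len(cfg@nRoots), function(i) {
      a <- stats::runif(1, 0, 2 * pi)
      pos <- ctr + radius * c(cos(a), sin(a))
      # head towards a point near the centre
      tgt <- ctr + stats::runif(2, -0.2, 0.2) * min(H, W)
      list(pos = pos, heading = atan2(tgt[2] - pos[2], tgt[1] - pos[1]),
           width = cfg@rootWidth, steps = cfg@maxDepth)
    })
    while (length(queue)) {
      wk <- queue[[1]]
      queue <- queue[-1]
      pos <- wk$pos; heading <- wk$heading; width <- wk$width
      steps <- wk$steps
      while (steps > 0 && width >= cfg@minWidth && inBounds(pos, H, W)) {
        heading <- heading + stats::rnorm(1, 0, cfg@angleJitterSd)
        nxt <- pos + cfg@stepLen * c(cos(heading), sin(heading))
        mask <- strokeRect(mask, pos, nxt, width)
        if (stats::runif(1) < cfg@branchProb) {
          side <- sample(c(-1, 1), 1)
          queue <- c(queue, list(list(
            pos = nxt,
            heading = heading + side * stats::runif(1, 20, 50) * pi / 180,
            width = width * cfg@widthDecay,
            steps = steps)))
        }
        pos <- nxt
        steps <- steps - 1
      }
    }
  })
  mask
}

inBounds <- function(pos, H, W) {
  pos[1] >= 1 && pos[1] <= W && pos[2] >= 1 && pos[2] <= H
}

## Rasterize a rectangular (butt-ended) stroke from p0 to p1 of the given
## width: pixels whose centre projects onto the segment within [0, len] and
## lies within width/2 of the axis.
strokeRect <- function(mask, p0, p1, width) {
  H <- nrow(mask); W <- ncol(mask)
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) return(mask)
  u <- v / len
  half <- width / 2
  xr <- max(1L, floor(min(p0[1], p1[1]) - half)):min(W, ceiling(max(p0[1], p1[1]) + half))
  yr <- max(1L, floor(min(p0[2], p1[2]) - half)):min(H, ceiling(max(p0[2], p1[2]) + half))
  if (!length(xr) || !length(yr)) return(mask)
  gx <- matrix(xr, length(yr), length(xr), byrow = TRUE) - p0[1]
  gy <- matrix(yr, length(yr), length(xr)) - p0[2]
  along <- gx * u[1] + gy * u[2]
  perp <- abs(-gx * u[2] + gy * u[1])
  hit <- along >= 0 & along <= len & perp <= half
  sub <- mask[yr, xr, drop = FALSE]
  sub[hit] <- 1
  mask[yr, xr] <- sub
  mask
}

#' Render a vessel mask as a fundus-like photograph
#'
#' Pixels outside the circular field of view (radius
#' `fovRadiusFrac * min(H, W) / 2`) are black.  Inside, intensity is
#' `backgroundLevel` plus a linear illumination ramp, minus
#' `vesselContrast` times a lightly blurred copy of the mask, plus Gaussian
#' noise, clipped to `[0, 1]`.  The red channel carries full intensity and
#' green/blue are attenuated to mimic the fundus tint.
#'
#' @param mask H x W binary matrix.
#' @param cfg a [FundusRenderConfig-class].
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
renderFundusImage <- function(mask, cfg) {
  stopifnot(is(cfg, "FundusRenderConfig"))
  validObject(cfg)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  H <- nrow(mask); W <- ncol(mask)
  soft <- blur3(mask)
  gx <- matrix((seq_len(W) - 1) / max(1, W - 1) - 0.5, H, W, byrow = TRUE)
  gy <- matrix((seq_len(H) - 1) / max(1, H - 1) - 0.5, H, W)
  v <- cfg@backgroundLevel + cfg@illuminationGradient * (gx + gy) -
    cfg@vesselContrast * soft
  if (cfg@noiseSd > 0) {
    v <- v + withr::with_seed(cfg@seed, matrix(stats::rnorm(H * W, 0, cfg@noiseSd), H, W))
  }
  v <- pmin(pmax(v, 0), 1)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  r2 <- (cfg@fovRadiusFrac * min(H, W) / 2)^2
  fov <- (matrix((seq_len(W) - cx)^2, H, W, byrow = TRUE) +
            matrix((seq_len(H) - cy)^2, H, W)) <= r2
  v <- v * fov
  array(c(v, 0.55 * v, 0.35 * v), c(H, W, 3))
}

## separable 3x3 binomial blur with edge replication
blur3 <- function(x) {
  pad <- rbind(x[1, , drop = FALSE], x, x[nrow(x), , drop = FALSE])
  y <- (pad[seq_len(nrow(x)), , drop = FALSE] +
          2 * pad[seq_len(nrow(x)) + 1L, , drop = FALSE] +
          pad[seq_len(nrow(x)) + 2L, , drop = FALSE]) / 4
  pad <- cbind(y[, 1, drop = FALSE], y, y[, ncol(y), drop = FALSE])
  (pad[, seq_len(ncol(x)), drop = FALSE] +
      2 * pad[, seq_len(ncol(x)) + 1L, drop = FALSE] +
      pad[, seq_len(ncol(x)) + 2L, drop = FALSE]) / 4
}

#' Apply one random geometric augmentation draw
#'
#' Draws a rotation in `[-maxRotationDeg, maxRotationDeg]`, x/y shifts in
#' `[-shiftFrac, shiftFrac]` of each dimension, a zoom factor in
#' `1 +/- maxZoomFrac`, and (if enabled) a horizontal flip with probability
#' one half, then applies the same geometry to the image (bilinear) and the
#' mask (nearest-neighbour, re-binarized).  Regions mapped from outside the
#' source are filled with 0, matching the dark field-of-view exterior.
#'
#' @param s a [FundusSample-class].
#' @param cfg an [AugmentConfig-class].
#' @param drawSeed seed for this draw.
#' @return augmented [FundusSample-class] of the same size.
#' @export
augmentSample <- function(s, cfg, drawSeed = cfg@seed) {
  stopifnot(is(s, "FundusSample"), is(cfg, "AugmentConfig"))
  H <- nrow(s@mask); W <- ncol(s@mask)
  draw <- withr::with_seed(drawSeed, list(
    theta = stats::runif(1, -cfg@maxRotationDeg, cfg@maxRotationDeg) * pi / 180,
    tx = stats::runif(1, -cfg@shiftFrac, cfg@shiftFrac) * W,
    ty = stats::runif(1, -cfg@shiftFrac, cfg@shiftFrac) * H,
    zoom = stats::runif(1, 1 - cfg@maxZoomFrac, 1 + cfg@maxZoomFrac),
    flip = cfg@hflip && stats::runif(1) < 0.5))
  img <- affineWarp(s@image, draw, bilinear = TRUE)
  msk <- affineWarp(s@mask, draw, bilinear = FALSE)
  fundusSample(s@id, img, (msk >= 0.5) * 1, s@source)
}

## Inverse-mapping affine warp about the image centre.  Forward model:
## dst = zoom * R(theta) * F * (src - ctr) + ctr + t, so sampling inverts it.
affineWarp <- function(x, draw, bilinear) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  nch <- if (length(d) == 3L) d[3] else 1L
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  dx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - draw$tx
  dy <- matrix(seq_len(H), H, W) - cy - draw$ty
  ct <- cos(draw$theta); st <- sin(draw$theta)
  # inverse rotation + inverse zoom
  sx <- (ct * dx + st * dy) / draw$zoom
  sy <- (-st * dx + ct * dy) / draw$zoom
  if (draw$flip) sx <- -sx
  sx <- sx + cx
  sy <- sy + cy
  out <- array(0, d)
  if (bilinear) {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    gather <- function(ch, xi, yi) {
      ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
      v <- matrix(0, H, W)
      v[ok] <- ch[cbind(yi[ok], xi[ok])]
      v
    }
    for (c in seq_len(nch)) {
      ch <- if (nch == 1L) x else x[, , c]
      v <- gather(ch, x0, y0) * (1 - fx) * (1 - fy) +
        gather(ch, x0 + 1, y0) * fx * (1 - fy) +
        gather(ch, x0, y0 + 1) * (1 - fx) * fy +
        gather(ch, x0 + 1, y0 + 1) * fx * fy
      if (nch == 1L) out <- v else out[, , c] <- v
    }
  } else {
    xi <- round(sx); yi <- round(sy)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    for (c in seq_len(nch)) {
      ch <- if (nch == 1L) x else x[, , c]
      v <- matrix(0, H, W)
      v[ok] <- ch[cbind(yi[ok], xi[ok])]
      if (nch == 1L) out <- v else out[, , c] <- v
    }
  }
  out
}

#' Generate a synthetic dataset
#'
#' Produces `n` fundus-like samples with exact vessel ground truth; each
#' sample uses tree/render sub-seeds derived deterministically from `seed`,
#' and ids are `synth_0000`, `synth_0001`, ...
#'
#' @param n number of samples (>= 1).
#' @param treeCfg a [VesselTreeConfig-class] (seed slot is overridden per
#'   sample).
#' @param renderCfg a [FundusRenderConfig-class] (seed likewise).
#' @param seed master seed.
#' @return list of [FundusSample-class] objects with `source = "synthetic"`.
#' @export
makeSyntheticDataset <- function(n, treeCfg = vesselTreeConfig(),
                                 renderCfg = fundusRenderConfig(), seed = 42L) {
  if (n < 1L) stop("argument error: n must be >= 1")
  subseeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  lapply(seq_len(n), function(i) {
    tc <- treeCfg; tc@seed <- subseeds[2L * i - 1L]
    rc <- renderCfg; rc@seed <- subseeds[2L * i]
    mask <- generateVesselMask(tc)
    img <- renderFundusImage(mask, rc)
    fundusSample(sprintf("synth_%04d", i - 1L), img, mask, "synthetic")
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `images/` and `masks/` PNG folders plus a `manifest.csv` (id,
#' image, mask) — the layout [loadDataset()] reads back.
#'
#' @param samples list of [FundusSample-class] objects.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    ip <- file.path(dir, "images", paste0(s@id, ".png"))
    mp <- file.path(dir, "masks", paste0(s@id, ".png"))
    png::writePNG(s@image, ip)
    png::writePNG(s@mask, mp)
    data.frame(id = s@id, image = ip, mask = mp)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
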