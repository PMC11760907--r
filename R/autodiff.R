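## Minimal reverse-mode automatic differentiation over dense R arrays.
##
## A forward pass executed inside `vsWithTape()` records every operation on a
## tape (topological order); `vsBackward()` walks the tape in reverse and
## accumulates gradients into the nodes.  Parameters are off-tape nodes that
## persist across steps; everything else is rebuilt each forward pass.
## Heavy kernels (convolutions, pooling) live in src/conv_ops.cpp; the rest is
## vectorized R.  All image tensors are [H, W, C, N]; token tensors are
## [T, D, N].

.vs <- new.env(parent = emptyenv())
.vs$tape <- NULL
.vs$training <- FALSE

vsNode <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd
}

#' @noRd
vsParam <- function(value) {
  nd <- vsNode(value)
  nd$is_param <- TRUE
  nd
}

vsTracing <- function() !is.null(.vs$tape)

vsRecord <- function(nd) {
  tp <- .vs$tape
  tp$k <- tp$k + 1L
  if (tp$k > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", max(64L, length(tp$nodes))))
  tp$nodes[[tp$k]] <- nd
  invisible(nd)
}

vsAcc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' Run an expression with gradient recording enabled
#' @noRd
vsWithTape <- function(expr) {
  old <- .vs$tape
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  .vs$tape <- tp
  on.exit(.vs$tape <- old)
  value <- force(expr)
  list(value = value, tape = tp)
}

#' Reverse pass: seed the loss gradient and walk the tape backwards
#' @noRd
vsBackward <- function(tape, loss) {
  loss$grad <- 1
  if (tape$k > 0L) {
    for (i in seq.int(tape$k, 1L)) {
      nd <- tape$nodes[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward()
    }
  }
  invisible(NULL)
}

vsSetTraining <- function(on) {
  old <- .vs$training
  .vs$training <- isTRUE(on)
  invisible(old)
}

## ---- elementwise ----------------------------------------------------------

opRelu <- function(x) {
  v <- x$value
  out <- vsNode(v * (v > 0))
  if (vsTracing()) {
    out$backward <- function() vsAcc(x, out$grad * (v > 0))
    vsRecord(out)
  }
  out
}

opSigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() vsAcc(x, out$grad * y * (1 - y))
    vsRecord(out)
  }
  out
}

opAdd <- function(x, y) {
  out <- vsNode(x$value + y$value)
  if (vsTracing()) {
    out$backward <- function() {
      vsAcc(x, out$grad)
      vsAcc(y, out$grad)
    }
    vsRecord(out)
  }
  out
}

opScale <- function(x, s) {
  out <- vsNode(x$value * s)
  if (vsTracing()) {
    out$backward <- function() vsAcc(x, out$grad * s)
    vsRecord(out)
  }
  out
}

## ---- image-tensor ops [H, W, C, N] ---------------------------------------

## whether a node participates in the backward pass (parameter or recorded
## intermediate); gradients into pure leaf constants are skipped
vsNeedsGrad <- function(nd) isTRUE(nd$is_param) || !is.null(nd$backward)

opConv2d <- function(x, w, b, stride = 1L, pad = NULL, dil = 1L) {
  kh <- dim(w$value)[1]
  if (is.null(pad)) pad <- as.integer(dil * (kh - 1L) / 2L) # 'same' for odd k, stride 1
  out <- vsNode(cpp_conv2d_fwd(x$value, w$value, b$value,
                               as.integer(stride), as.integer(pad), as.integer(dil)))
  if (vsTracing()) {
    out$backward <- function() {
      need_dx <- vsNeedsGrad(x)
      g <- cpp_conv2d_bwd(x$value, w$value, out$grad,
                          as.integer(stride), as.integer(pad), as.integer(dil),
                          need_dx)
      if (need_dx) vsAcc(x, g$dx)
      vsAcc(w, g$dw); vsAcc(b, g$db)
    }
    vsRecord(out)
  }
  out
}

opConvT2 <- function(x, w, b) {
  out <- vsNode(cpp_convt2_fwd(x$value, w$value, b$value))
  if (vsTracing()) {
    out$backward <- function() {
      g <- cpp_convt2_bwd(x$value, w$value, out$grad)
      vsAcc(x, g$dx); vsAcc(w, g$dw); vsAcc(b, g$db)
    }
    vsRecord(out)
  }
  out
}

opMaxPool2 <- function(x) {
  d <- dim(x$value)
  fw <- cpp_maxpool2_fwd(x$value)
  out <- vsNode(fw$y)
  if (vsTracing()) {
    idx <- fw$idx
    out$backward <- function() vsAcc(x, cpp_maxpool2_bwd(out$grad, idx, d[1], d[2]))
    vsRecord(out)
  }
  out
}

opConcatCh <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(dims, `[`, integer(1), 3L)
  d0 <- dims[[1]]
  y <- array(0, c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , (at + 1L):(at + cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      at <- 0L
      for (i in seq_along(xs)) {
        vsAcc(xs[[i]], out$grad[, , (at + 1L):(at + cs[i]), , drop = FALSE])
        at <- at + cs[i]
      }
    }
    vsRecord(out)
  }
  out
}

## Batch normalization per channel over (H, W, N).  `state` is an environment
## holding running moments under `key`; training mode uses batch statistics
## and updates the running ones, eval mode uses the running ones.
opBatchNorm <- function(x, gamma, beta, state, key, momentum = 0.9, eps = 1e-5) {
  d <- dim(x$value)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- HW * N
  xm <- x$value
  dim(xm) <- c(HW, C * N) # columns ordered (c fastest within each n)
  chanSum <- function(M) rowSums(matrix(colSums(M), C, N)) # per-channel totals
  if (.vs$training) {
    mu <- chanSum(xm) / m
    v <- chanSum(xm * xm) / m - mu^2
    v[v < 0] <- 0
    rs <- state[[key]]
    if (is.null(rs)) rs <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]] <- list(mean = momentum * rs$mean + (1 - momentum) * mu,
                         var = momentum * rs$var + (1 - momentum) * v)
  } else {
    rs <- state[[key]]
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean
    v <- rs$var
  }
  inv <- 1 / sqrt(v + eps)
  # length HW*C vectors recycle over the N sample blocks of xm
  scl <- rep(gamma$value * inv, each = HW)
  sft <- rep(beta$value - gamma$value * inv * mu, each = HW)
  ym <- xm * scl + sft
  dim(ym) <- d
  out <- vsNode(ym)
  if (vsTracing()) {
    batch_stats <- .vs$training
    out$backward <- function() {
      gm <- out$grad
      dim(gm) <- c(HW, C * N)
      xhat <- xm * rep(inv, each = HW) - rep(inv * mu, each = HW)
      vsAcc(gamma, chanSum(gm * xhat))
      vsAcc(beta, chanSum(gm))
      dxhat <- gm * rep(gamma$value, each = HW)
      if (batch_stats) {
        m1 <- chanSum(dxhat) / m
        m2 <- chanSum(dxhat * xhat) / m
        dxm <- (dxhat - rep(m1, each = HW) - xhat * rep(m2, each = HW)) *
          rep(inv, each = HW)
      } else {
        dxm <- dxhat * rep(inv, each = HW)
      }
      dim(dxm) <- d
      vsAcc(x, dxm)
    }
    vsRecord(out)
  }
  out
}

## Fixed bilinear 2x upsampling (linear map; backward is its adjoint).
opUpsample2Bilinear <- function(x) {
  d <- dim(x$value)
  Ah <- bilinearMatrix(d[1])
  Aw <- bilinearMatrix(d[2])
  v <- x$value
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    y[, , c, n] <- Ah %*% v[, , c, n] %*% t(Aw)
  }
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      g <- out$grad
      dx <- array(0, d)
      for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
        dx[, , c, n] <- t(Ah) %*% g[, , c, n] %*% Aw
      }
      vsAcc(x, dx)
    }
    vsRecord(out)
  }
  out
}

bilinearMatrix <- function(H) {
  # rows: output coords 0..2H-1 sampled at src = (i + 0.5)/2 - 0.5, clamped
  A <- matrix(0, 2 * H, H)
  for (i in seq_len(2 * H)) {
    s <- (i - 1 + 0.5) / 2 - 0.5
    s <- min(max(s, 0), H - 1)
    lo <- floor(s)
    fr <- s - lo
    A[i, lo + 1] <- A[i, lo + 1] + (1 - fr)
    if (fr > 0) A[i, lo + 2] <- A[i, lo + 2] + fr
  }
  A
}

## ---- token-tensor ops [T, D, N] -------------------------------------------

tokFold <- function(v) {
  d <- dim(v)
  matrix(aperm(v, c(1, 3, 2)), d[1] * d[3], d[2])
}

tokUnfold <- function(m, Tn, N) {
  aperm(array(m, c(Tn, N, ncol(m))), c(1, 3, 2))
}

## y[,,n] = x[,,n] %*% W + b
opLin3 <- function(x, w, b) {
  d <- dim(x$value)
  xm <- tokFold(x$value)
  ym <- sweep(xm %*% w$value, 2, b$value, `+`)
  out <- vsNode(tokUnfold(ym, d[1], d[3]))
  if (vsTracing()) {
    out$backward <- function() {
      gm <- tokFold(out$grad)
      vsAcc(w, crossprod(xm, gm))
      vsAcc(b, colSums(gm))
      vsAcc(x, tokUnfold(gm %*% t(w$value), d[1], d[3]))
    }
    vsRecord(out)
  }
  out
}

## scores[,,n] = q[,,n] %*% t(k[,,n])
opBmmNT <- function(q, k) {
  d <- dim(q$value)
  N <- d[3]
  y <- array(0, c(d[1], dim(k$value)[1], N))
  for (n in seq_len(N)) y[, , n] <- q$value[, , n] %*% t(k$value[, , n])
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      dq <- array(0, dim(q$value)); dk <- array(0, dim(k$value))
      for (n in seq_len(N)) {
        g <- out$grad[, , n]
        dq[, , n] <- g %*% k$value[, , n]
        dk[, , n] <- t(g) %*% q$value[, , n]
      }
      vsAcc(q, dq); vsAcc(k, dk)
    }
    vsRecord(out)
  }
  out
}

## y[,,n] = a[,,n] %*% v[,,n]
opBmm <- function(a, v) {
  da <- dim(a$value); dv <- dim(v$value)
  N <- da[3]
  y <- array(0, c(da[1], dv[2], N))
  for (n in seq_len(N)) y[, , n] <- a$value[, , n] %*% v$value[, , n]
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      dA <- array(0, da); dV <- array(0, dv)
      for (n in seq_len(N)) {
        g <- out$grad[, , n]
        dA[, , n] <- g %*% t(v$value[, , n])
        dV[, , n] <- t(a$value[, , n]) %*% g
      }
      vsAcc(a, dA); vsAcc(v, dV)
    }
    vsRecord(out)
  }
  out
}

## softmax over dim 2 (keys) of [Tq, Tk, N]
opSoftmax3 <- function(x) {
  v <- x$value
  d <- dim(v)
  y <- array(0, d)
  for (n in seq_len(d[3])) {
    s <- v[, , n, drop = TRUE]
    if (is.null(dim(s))) s <- matrix(s, d[1], d[2])
    s <- exp(s - apply(s, 1, max))
    y[, , n] <- s / rowSums(s)
  }
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      dx <- array(0, d)
      for (n in seq_len(d[3])) {
        yn <- matrix(y[, , n], d[1], d[2])
        gn <- matrix(out$grad[, , n], d[1], d[2])
        dx[, , n] <- yn * (gn - rowSums(gn * yn))
      }
      vsAcc(x, dx)
    }
    vsRecord(out)
  }
  out
}

## layer normalization over the embedding dim (dim 2) of [T, D, N]
opLayerNorm3 <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  xm <- tokFold(x$value)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  ym <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  out <- vsNode(tokUnfold(ym, d[1], d[3]))
  if (vsTracing()) {
    out$backward <- function() {
      gm <- tokFold(out$grad)
      vsAcc(gamma, colSums(gm * xhat))
      vsAcc(beta, colSums(gm))
      dxhat <- sweep(gm, 2, gamma$value, `*`)
      dxm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
      vsAcc(x, tokUnfold(dxm, d[1], d[3]))
    }
    vsRecord(out)
  }
  out
}

## add a learned [T, D] positional embedding, broadcast over samples
opAddPos <- function(x, p) {
  d <- dim(x$value)
  out <- vsNode(x$value + array(p$value, d))
  if (vsTracing()) {
    out$backward <- function() {
      vsAcc(x, out$grad)
      vsAcc(p, rowSums(out$grad, dims = 2))
    }
    vsRecord(out)
  }
  out
}

opConcatD <- function(xs) {
  ds <- vapply(xs, function(x) dim(x$value)[2], integer(1))
  d0 <- dim(xs[[1]]$value)
  y <- array(0, c(d0[1], sum(ds), d0[3]))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, (at + 1L):(at + ds[i]), ] <- xs[[i]]$value
    at <- at + ds[i]
  }
  out <- vsNode(y)
  if (vsTracing()) {
    out$backward <- function() {
      at <- 0L
      for (i in seq_along(xs)) {
        vsAcc(xs[[i]], out$grad[, (at + 1L):(at + ds[i]), , drop = FALSE])
        at <- at + ds[i]
      }
    }
    vsRecord(out)
  }
  out
}

## reshape [h, w, C, N] -> [h*w, C, N] (one token per spatial position) and back
opToTokens <- function(x) {
  d <- dim(x$value)
  out <- vsNode(array(x$value, c(d[1] * d[2], d[3], d[4])))
  if (vsTracing()) {
    out$backward <- function() vsAcc(x, array(out$grad, d))
    vsRecord(out)
  }
  out
}

opToMap <- function(x, h, w) {
  d <- dim(x$value)
  out <- vsNode(array(x$value, c(h, w, d[2], d[3])))
  if (vsTracing()) {
    out$backward <- function() vsAcc(x, array(out$grad, d))
    vsRecord(out)
  }
  out
}

## ---- loss -----------------------------------------------------------------

## Pixel-wise binary cross-entropy between a probability node and a 0/1 target
## array; probabilities are clipped to [eps, 1-eps] in both value and gradient.
opBceLoss <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  n <- length(p)
  val <- -sum(target * log(p) + (1 - target) * log(1 - p)) / n
  out <- vsNode(val)
  if (vsTracing()) {
    out$backward <- function() {
      g <- out$grad * (p - target) / (p * (1 - p)) / n
      dim(g) <- dim(pred$value)
      vsAcc(pred, g)
    }
    vsRecord(out)
  }
  out
}
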