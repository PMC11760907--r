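## Layer constructors over the autodiff ops.  A "module" is an environment
## holding named parameter nodes (`params`), batch-norm running statistics
## (`state`), and a `forward(x, ...)` closure assembled by the architecture
## builders.  Layer constructors register their parameters at build time
## (under the builder's seeded RNG) and return closures used in forward().

vsModule <- function() {
  mod <- new.env(parent = emptyenv())
  mod$params <- list()
  mod$state <- new.env(parent = emptyenv())
  mod
}

addParam <- function(mod, name, value) {
  if (!is.null(mod$params[[name]])) stop("duplicate parameter name: ", name)
  p <- vsParam(value)
  mod$params[[name]] <- p
  p
}

heConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

glorotMat <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout)
}

## 2-D convolution layer, optional batch norm and activation
layerConv <- function(mod, name, k, cin, cout, stride = 1L, dil = 1L,
                      bn = FALSE, act = c("relu", "none", "sigmoid"),
                      bias = TRUE) {
  act <- match.arg(act)
  w <- addParam(mod, paste0(name, ".w"), heConv(k, k, cin, cout))
  b <- if (bias) addParam(mod, paste0(name, ".b"), numeric(cout))
    else vsNode(numeric(cout)) # fixed zero bias (e.g. the meta hidden layer)
  if (bn) {
    g <- addParam(mod, paste0(name, ".bn.g"), rep(1, cout))
    bb <- addParam(mod, paste0(name, ".bn.b"), numeric(cout))
  }
  pad <- as.integer(dil * (k - 1L) %/% 2L)
  function(x) {
    y <- opConv2d(x, w, b, stride = stride, pad = pad, dil = dil)
    if (bn) y <- opBatchNorm(y, g, bb, mod$state, name)
    switch(act, relu = opRelu(y), sigmoid = opSigmoid(y), none = y)
  }
}

## 2x2 stride-2 transposed convolution (up-convolution)
layerConvT2 <- function(mod, name, cin, cout) {
  w <- addParam(mod, paste0(name, ".w"), heConv(2, 2, cin, cout))
  b <- addParam(mod, paste0(name, ".b"), numeric(cout))
  function(x) opConvT2(x, w, b)
}

## double 3x3 conv + ReLU, the U-Net building block
layerDoubleConv <- function(mod, name, cin, cout, bn = FALSE) {
  c1 <- layerConv(mod, paste0(name, ".c1"), 3L, cin, cout, bn = bn)
  c2 <- layerConv(mod, paste0(name, ".c2"), 3L, cout, cout, bn = bn)
  function(x) c2(c1(x))
}

## up-sampling step: transposed conv (default) or fixed bilinear + 3x3 conv
layerUp <- function(mod, name, cin, cout, mode = c("transpose", "bilinear")) {
  mode <- match.arg(mode)
  if (mode == "transpose") {
    layerConvT2(mod, name, cin, cout)
  } else {
    cv <- layerConv(mod, paste0(name, ".c"), 3L, cin, cout, act = "none")
    function(x) cv(opUpsample2Bilinear(x))
  }
}

## ResNet bottleneck block: 1x1 -> 3x3 (stride) -> 1x1, BN + ReLU, shortcut
layerResBlock <- function(mod, name, cin, cmid, cout, stride = 1L) {
  c1 <- layerConv(mod, paste0(name, ".c1"), 1L, cin, cmid, bn = TRUE)
  c2 <- layerConv(mod, paste0(name, ".c2"), 3L, cmid, cmid, stride = stride, bn = TRUE)
  c3 <- layerConv(mod, paste0(name, ".c3"), 1L, cmid, cout, bn = TRUE, act = "none")
  proj <- NULL
  if (stride != 1L || cin != cout) {
    proj <- layerConv(mod, paste0(name, ".proj"), 1L, cin, cout, stride = stride,
                      bn = TRUE, act = "none")
  }
  function(x) {
    sc <- if (is.null(proj)) x else proj(x)
    opRelu(opAdd(c3(c2(c1(x))), sc))
  }
}

## Pre-norm transformer encoder block over [T, D, N] tokens
layerTransformerBlock <- function(mod, name, d_model, n_heads, mlp_ratio = 4) {
  if (d_model %% n_heads != 0) stop("n_heads must divide the token embedding dim")
  dh <- d_model %/% n_heads
  ln1g <- addParam(mod, paste0(name, ".ln1.g"), rep(1, d_model))
  ln1b <- addParam(mod, paste0(name, ".ln1.b"), numeric(d_model))
  ln2g <- addParam(mod, paste0(name, ".ln2.g"), rep(1, d_model))
  ln2b <- addParam(mod, paste0(name, ".ln2.b"), numeric(d_model))
  heads <- lapply(seq_len(n_heads), function(h) {
    list(
      wq = addParam(mod, sprintf("%s.h%d.wq", name, h), glorotMat(d_model, dh)),
      bq = addParam(mod, sprintf("%s.h%d.bq", name, h), numeric(dh)),
      wk = addParam(mod, sprintf("%s.h%d.wk", name, h), glorotMat(d_model, dh)),
      bk = addParam(mod, sprintf("%s.h%d.bk", name, h), numeric(dh)),
      wv = addParam(mod, sprintf("%s.h%d.wv", name, h), glorotMat(d_model, dh)),
      bv = addParam(mod, sprintf("%s.h%d.bv", name, h), numeric(dh))
    )
  })
  wo <- addParam(mod, paste0(name, ".wo"), glorotMat(d_model, d_model))
  bo <- addParam(mod, paste0(name, ".bo"), numeric(d_model))
  dm <- as.integer(round(mlp_ratio * d_model))
  w1 <- addParam(mod, paste0(name, ".mlp.w1"), glorotMat(d_model, dm))
  b1 <- addParam(mod, paste0(name, ".mlp.b1"), numeric(dm))
  w2 <- addParam(mod, paste0(name, ".mlp.w2"), glorotMat(dm, d_model))
  b2 <- addParam(mod, paste0(name, ".mlp.b2"), numeric(d_model))
  scale <- 1 / sqrt(dh)
  function(x) {
    h <- opLayerNorm3(x, ln1g, ln1b)
    outs <- lapply(heads, function(hd) {
      q <- opLin3(h, hd$wq, hd$bq)
      k <- opLin3(h, hd$wk, hd$bk)
      v <- opLin3(h, hd$wv, hd$bv)
      a <- opSoftmax3(opScale(opBmmNT(q, k), scale))
      opBmm(a, v)
    })
    att <- opLin3(opConcatD(outs), wo, bo)
    x <- opAdd(x, att)
    m <- opLayerNorm3(x, ln2g, ln2b)
    m <- opLin3(opRelu(opLin3(m, w1, b1)), w2, b2)
    opAdd(x, m)
  }
}

## ---- optimizer ------------------------------------------------------------

## Adam over a module's parameter list; state kept in an environment so a
## training loop can step repeatedly.
adamInit <- function(params, lr = 0.01, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adamStep <- function(params, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- st$b1 * st$m[[nm]] + (1 - st$b1) * g
    st$v[[nm]] <- st$b2 * st$v[[nm]] + (1 - st$b2) * g * g
    p$value <- p$value - st$lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  invisible(NULL)
}

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## deep copy / restore of parameter values (checkpointing)
paramSnapshot <- function(params) lapply(params, function(p) p$value)

paramRestore <- function(params, snap) {
  for (nm in names(snap)) params[[nm]]$value <- snap[[nm]]
  invisible(NULL)
}
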