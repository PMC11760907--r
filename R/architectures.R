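## The four base segmentation networks.  All builders share one contract:
## input [H, W, 3, N] in [0, 1], output [H, W, 1, N] strictly in (0, 1),
## spatial size preserved, seeded deterministic initialization.  Encoder
## parameters are namespaced under "enc." so they can be frozen as a group.

## ---- U-Net ----------------------------------------------------------------

#' Build a U-Net segmentation model
#'
#' Classic encoder-decoder: `depth` encoder blocks of two 3x3 conv + ReLU
#' followed by 2x2 max pooling, channels doubling per level from
#' `baseChannels`; a two-conv bottleneck at `2^depth * baseChannels`
#' channels; a mirrored decoder with up-convolutions, skip concatenation
#' from the matching encoder level and two 3x3 conv + ReLU per level; and a
#' 1x1 convolution with sigmoid producing the per-pixel vessel probability.
#'
#' @param spec an [ArchitectureSpec-class] with `name = "unet"`.
#' @return A [SegmentationModel-class].
#' @export
buildUnet <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  if (spec@name != "unet") stop("spec name must be 'unet'")
  validObject(spec)
  buildUnetLike(spec, transformer_bottleneck = FALSE)
}

#' Build the transformer-bottleneck U-Net (CTU-Net)
#'
#' Identical to [buildUnet()] except at the bottleneck: the deepest feature
#' map is projected to the bottleneck width, flattened into one token per
#' spatial position, given a learned positional embedding, passed through
#' `transformer$n_blocks` pre-norm transformer blocks (multi-head
#' self-attention plus a feed-forward of width `mlp_ratio * dim`, each with
#' residual connection and layer normalization), and reshaped back into a
#' spatial map consumed by the standard U-Net decoder.
#'
#' @param spec an [ArchitectureSpec-class] with `name = "ctu_net"`.
#' @return A [SegmentationModel-class].
#' @export
buildCtuNet <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  if (spec@name != "ctu_net") stop("spec name must be 'ctu_net'")
  validObject(spec)
  buildUnetLike(spec, transformer_bottleneck = TRUE)
}

buildUnetLike <- function(spec, transformer_bottleneck) {
  base <- spec@baseChannels
  depth <- spec@depth
  mod <- vsModule()
  mod$use_skips <- TRUE
  withr::with_seed(spec@seed, {
    enc <- vector("list", depth)
    ch <- 3L
    for (i in seq_len(depth)) {
      co <- base * 2L^(i - 1L)
      enc[[i]] <- layerDoubleConv(mod, sprintf("enc.l%d", i), ch, co)
      ch <- co
    }
    cb <- 2L * ch # bottleneck width
    if (transformer_bottleneck) {
      hb <- spec@inputSize[1] %/% 2L^depth
      wb <- spec@inputSize[2] %/% 2L^depth
      embed <- layerConv(mod, "bott.embed", 1L, ch, cb, act = "none")
      pos <- addParam(mod, "bott.pos",
                      matrix(stats::rnorm(hb * wb * cb, sd = 0.02), hb * wb, cb))
      blocks <- lapply(seq_len(spec@transformer$n_blocks), function(k) {
        layerTransformerBlock(mod, sprintf("bott.tb%d", k), cb,
                              spec@transformer$n_heads,
                              spec@transformer$mlp_ratio)
      })
      bott <- function(x) {
        tok <- opAddPos(opToTokens(embed(x)), pos)
        for (blk in blocks) tok <- blk(tok)
        opToMap(tok, hb, wb)
      }
    } else {
      bott <- layerDoubleConv(mod, "bott", ch, cb)
    }
    ups <- vector("list", depth)
    dec <- vector("list", depth)
    chb <- cb
    for (i in seq.int(depth, 1L)) {
      co <- base * 2L^(i - 1L)
      ups[[i]] <- layerUp(mod, sprintf("up%d", i), chb, co, mode = spec@upsampling)
      dec[[i]] <- layerDoubleConv(mod, sprintf("dec%d", i), 2L * co, co)
      chb <- co
    }
    head <- layerConv(mod, "head", 1L, base, 1L, act = "sigmoid")
  })
  mod$forward <- function(x) {
    skips <- vector("list", depth)
    h <- x
    for (i in seq_len(depth)) {
      h <- enc[[i]](h)
      skips[[i]] <- h
      h <- opMaxPool2(h)
    }
    h <- bott(h)
    for (i in seq.int(depth, 1L)) {
      h <- ups[[i]](h)
      s <- if (isTRUE(mod$use_skips)) skips[[i]] else vsNode(skips[[i]]$value * 0)
      h <- dec[[i]](opConcatCh(list(s, h)))
    }
    head(h)
  }
  new("SegmentationModel", spec = spec, module = mod)
}

## ---- ResNet50 encoder -----------------------------------------------------

## Standard ResNet50 layout scaled by base/64: 7x7 stride-2 stem, max pool,
## then four stages of bottleneck residual blocks (3, 4, 6, 3).  Returns taps
## at strides 2 (stem), 4, 8, 16 and 32.
resnetEncoder <- function(mod, base) {
  stem <- layerConv(mod, "enc.stem", 7L, 3L, base, stride = 2L, bn = TRUE)
  n_blocks <- c(3L, 4L, 6L, 3L)
  stages <- vector("list", 4L)
  cin <- base
  for (s in 1:4) {
    cmid <- base * 2L^(s - 1L)
    cout <- 4L * cmid
    blocks <- vector("list", n_blocks[s])
    for (b in seq_len(n_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[b]] <- layerResBlock(mod, sprintf("enc.s%d.b%d", s, b),
                                   cin, cmid, cout, stride = stride)
      cin <- cout
    }
    stages[[s]] <- blocks
  }
  list(
    forward = function(x) {
      t2 <- stem(x)                       # stride 2
      h <- opMaxPool2(t2)                 # stride 4
      taps <- vector("list", 5L)
      taps[[1]] <- t2
      for (s in 1:4) {
        for (blk in stages[[s]]) h <- blk(h)
        taps[[s + 1L]] <- h               # strides 4, 8, 16, 32
      }
      taps
    },
    channels = c(base, 4L * base, 8L * base, 16L * base, 32L * base)
  )
}

## Shared 5-step decoder from stride 32 back to full resolution with skip
## connections from the stride-16/8/4/2 taps (4 skips into 5 up steps).
resnetDecoder <- function(mod, in_ch, skip_ch, base, upsampling) {
  out_ch <- c(8L, 4L, 2L, 1L, 1L) * base
  ups <- vector("list", 5L)
  dec <- vector("list", 5L)
  ch <- in_ch
  for (i in 1:5) {
    ups[[i]] <- layerUp(mod, sprintf("dup%d", i), ch, out_ch[i], mode = upsampling)
    cat_ch <- out_ch[i] + if (i <= 4L) skip_ch[5L - i] else 0L
    dec[[i]] <- layerDoubleConv(mod, sprintf("ddec%d", i), cat_ch, out_ch[i])
    ch <- out_ch[i]
  }
  head <- layerConv(mod, "head", 1L, out_ch[5], 1L, act = "sigmoid")
  function(h, taps, use_skips = TRUE) {
    for (i in 1:5) {
      h <- ups[[i]](h)
      if (i <= 4L) {
        s <- taps[[5L - i]]
        if (!use_skips) s <- vsNode(s$value * 0)
        h <- opConcatCh(list(s, h))
      }
      h <- dec[[i]](h)
    }
    head(h)
  }
}

#' Build the customized ResNet50 segmentation model
#'
#' Encoder: the standard ResNet50 layout (7x7 stride-2 stem, max pooling,
#' four stages of 3/4/6/3 bottleneck residual blocks with batch norm, ReLU
#' and shortcut connections), width-scaled by `baseChannels / 64`.  Between
#' encoder and decoder a pyramid pooling module applies parallel 3x3
#' convolutions at the dilation rates in `ppmDilations`, concatenates the
#' branches and fuses them with a 1x1 convolution.  The decoder performs
#' five x2 upsampling steps with skip connections from the stem and each
#' stage, ending in a 1x1 convolution with sigmoid.
#'
#' @param spec an [ArchitectureSpec-class] with `name = "resnet50_seg"`.
#' @return A [SegmentationModel-class].
#' @export
buildResnet50Seg <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  if (spec@name != "resnet50_seg") stop("spec name must be 'resnet50_seg'")
  validObject(spec)
  checkBackboneWeights(spec)
  base <- spec@baseChannels
  mod <- vsModule()
  mod$use_skips <- TRUE
  withr::with_seed(spec@seed, {
    encdef <- resnetEncoder(mod, base)
    c4 <- encdef$channels[5]
    branch_ch <- max(1L, c4 %/% 4L)
    branches <- lapply(seq_along(spec@ppmDilations), function(i) {
      layerConv(mod, sprintf("ppm.d%d", spec@ppmDilations[i]), 3L, c4, branch_ch,
                dil = spec@ppmDilations[i])
    })
    fuse <- layerConv(mod, "ppm.fuse", 1L,
                      branch_ch * length(spec@ppmDilations), c4)
    decode <- resnetDecoder(mod, c4, encdef$channels[1:4], base, spec@upsampling)
  })
  mod$forward <- function(x) {
    taps <- encdef$forward(x)
    h <- taps[[5]]
    h <- fuse(opConcatCh(lapply(branches, function(br) br(h))))
    decode(h, taps, use_skips = isTRUE(mod$use_skips))
  }
  new("SegmentationModel", spec = spec, module = mod)
}

#' Build U-Net with a ResNet50 backbone
#'
#' Uses the ResNet50 stages as the feature extractor, tapping feature maps at
#' strides 2, 4, 8, 16 and 32, and decodes with the U-Net decoder
#' (up-convolution, skip concatenation of the four intermediate taps, double
#' 3x3 conv + ReLU per level, 1x1 sigmoid head).
#'
#' @param spec an [ArchitectureSpec-class] with `name = "unet_resnet_backbone"`.
#' @return A [SegmentationModel-class].
#' @export
buildUnetResnetBackbone <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  if (spec@name != "unet_resnet_backbone") stop("spec name must be 'unet_resnet_backbone'")
  validObject(spec)
  checkBackboneWeights(spec)
  base <- spec@baseChannels
  mod <- vsModule()
  mod$use_skips <- TRUE
  withr::with_seed(spec@seed, {
    encdef <- resnetEncoder(mod, base)
    decode <- resnetDecoder(mod, encdef$channels[5], encdef$channels[1:4],
                            base, spec@upsampling)
  })
  mod$forward <- function(x) {
    taps <- encdef$forward(x)
    decode(taps[[5]], taps, use_skips = isTRUE(mod$use_skips))
  }
  new("SegmentationModel", spec = spec, module = mod)
}

checkBackboneWeights <- function(spec) {
  if (spec@pretrainedBackbone)
    stop("pretrainedBackbone = TRUE requires a weights file; build with ",
         "pretrainedBackbone = FALSE and call loadBackboneWeights()")
  invisible(NULL)
}

#' Build a base model from its spec
#' @param spec an [ArchitectureSpec-class].
#' @return A [SegmentationModel-class].
#' @export
buildModel <- function(spec) {
  switch(spec@name,
         unet = buildUnet(spec),
         resnet50_seg = buildResnet50Seg(spec),
         unet_resnet_backbone = buildUnetResnetBackbone(spec),
         ctu_net = buildCtuNet(spec),
         stop("unknown architecture name: ", spec@name))
}

## ---- inference ------------------------------------------------------------

#' Predict vessel probability maps
#'
#' Runs the network in inference mode (batch norm uses running statistics;
#' no gradient recording), which is deterministic: the same batch always
#' yields the same output.
#'
#' @param object a [SegmentationModel-class].
#' @param batch an H x W x 3 image or an H x W x 3 x B batch, values in
#'   `[0, 1]`, spatial size matching `modelSpec(object)@inputSize`.
#' @param ... unused.
#' @return An H x W probability matrix (single image) or H x W x B array,
#'   values strictly in (0, 1).
#' @export
setMethod("predict", "SegmentationModel", function(object, batch, ...) {
  predictForward(object@module, object@spec@inputSize, batch)
})

predictForward <- function(mod, input_size, batch) {
  x <- asBatch(batch)
  d <- dim(x)
  if (d[1] != input_size[1] || d[2] != input_size[2])
    stop(sprintf("dimension mismatch: batch is %d x %d but the model expects %d x %d",
                 d[1], d[2], input_size[1], input_size[2]))
  old <- vsSetTraining(FALSE)
  on.exit(vsSetTraining(old))
  out <- mod$forward(vsNode(x))$value
  if (length(dim(batch)) == 3L) {
    matrix(out, d[1], d[2])
  } else {
    array(out, c(d[1], d[2], d[4]))
  }
}

asBatch <- function(batch) {
  d <- dim(batch)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("batch must be H x W x 3 or H x W x 3 x B")
  if (d[3] != 3L) stop("dimension mismatch: batch must have 3 channels")
  if (length(d) == 3L) dim(batch) <- c(d, 1L)
  batch
}

## ---- parameter utilities --------------------------------------------------

#' Freeze the encoder of a model
#'
#' Frozen parameter groups are excluded from optimizer updates (their
#' gradients are discarded), so e.g. a pretrained backbone stays fixed while
#' the decoder trains.
#'
#' @param model a [SegmentationModel-class].
#' @param prefixes parameter-name prefixes to freeze; defaults to the
#'   encoder namespace.
#' @return The model, invisibly (modified in place).
#' @export
freezeParameters <- function(model, prefixes = "enc.") {
  model@module$frozen <- unique(c(model@module$frozen, prefixes))
  invisible(model)
}

frozenMask <- function(mod) {
  if (is.null(mod$frozen)) return(rep(FALSE, length(mod$params)))
  nm <- names(mod$params)
  Reduce(`|`, lapply(mod$frozen, function(p) startsWith(nm, p)),
         rep(FALSE, length(nm)))
}

#' Text summary of a model's layers
#' @param object a [SegmentationModel-class].
#' @param ... unused.
#' @return data.frame of parameter tensors (name, shape, size), invisibly;
#'   also printed.
#' @export
setMethod("summary", "SegmentationModel", function(object, ...) {
  ps <- object@module$params
  df <- data.frame(
    name = names(ps),
    shape = vapply(ps, function(p) paste(dim(as.array(p$value)), collapse = "x"),
                   character(1)),
    n = vapply(ps, function(p) length(p$value), numeric(1)),
    row.names = NULL)
  cat(sprintf("SegmentationModel '%s': %d parameter tensors, %s parameters\n",
              object@spec@name, nrow(df), format(sum(df$n), big.mark = ",")))
  invisible(df)
})

## ---- checkpointing --------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the architecture spec, all parameter
#' values keyed by layer name, and the batch-norm running statistics; loading
#' rebuilds the model from the embedded spec and restores the state, so a
#' reloaded checkpoint reproduces the saved model's predictions exactly.
#'
#' @param model a [SegmentationModel-class] or [MetaModel-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint()` the path, invisibly; `loadCheckpoint()` the
#'   restored model.
#' @export
saveCheckpoint <- function(model, path) {
  mod <- model@module
  obj <- list(
    kind = class(model)[1],
    spec = if (is(model, "SegmentationModel")) model@spec else
      list(kInputs = model@kInputs, hiddenFilters = model@hiddenFilters),
    params = paramSnapshot(mod$params),
    state = as.list(mod$state))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  model <- if (obj$kind == "SegmentationModel") {
    buildModel(obj$spec)
  } else {
    buildMetaModel(obj$spec$kInputs, obj$spec$hiddenFilters)
  }
  stopifnot(identical(sort(names(model@module$params)), sort(names(obj$params))))
  paramRestore(model@module$params, obj$params)
  for (k in names(obj$state)) model@module$state[[k]] <- obj$state[[k]]
  model
}

#' Load externally trained backbone weights into a ResNet-based model
#'
#' Optional transfer-learning hook: reads an RDS file of arrays keyed by this
#' package's encoder parameter names and copies any matching entries.
#'
#' @param model a [SegmentationModel-class] with a ResNet encoder.
#' @param path RDS file of named weight arrays.
#' @return The model, invisibly (modified in place); the names restored are
#'   reported.
#' @export
loadBackboneWeights <- function(model, path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  w <- readRDS(path)
  hit <- intersect(names(w), names(model@module$params))
  for (nm in hit) {
    p <- model@module$params[[nm]]
    if (!identical(dim(as.array(p$value)), dim(as.array(w[[nm]]))))
      stop("shape mismatch for backbone weight: ", nm)
    p$value <- w[[nm]]
  }
  message(sprintf("restored %d of %d encoder tensors", length(hit),
                  sum(startsWith(names(model@module$params), "enc."))))
  invisible(model)
}
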