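# Fixture builders shared across tests.  Everything is generated in code;
# nothing is read from disk except files the tests write themselves.

# tiny deterministic synthetic samples
tinySamples <- function(n = 2, size = 32, seed = 11L) {
  makeSyntheticDataset(n, vesselTreeConfig(imageSize = c(size, size)),
                       fundusRenderConfig(), seed = seed)
}

# a reduced-width spec for fast architecture tests
tinySpec <- function(name, size = 32L, base = 4L, seed = 7L) {
  architectureSpec(name, inputSize = c(size, size), baseChannels = base,
                   seed = seed)
}

allArchitectures <- function() {
  c("unet", "ctu_net", "resnet50_seg", "unet_resnet_backbone")
}

# central-difference numerical gradient of f (scalar-valued) at x
numGrad <- function(f, x, h = 1e-5) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# analytic gradient of a scalar-node-valued builder wrt its input array
analyticGrad <- function(f_build, x0) {
  xn <- vesselStack:::vsParam(x0)
  res <- vesselStack:::vsWithTape(f_build(xn))
  vesselStack:::vsBackward(res$tape, res$value)
  xn$grad
}

# numeric gradient of the same builder
numericGradOf <- function(f_build, x0) {
  numGrad(function(x) {
    r <- vesselStack:::vsWithTape(f_build(vesselStack:::vsParam(x)))
    as.numeric(r$value$value)
  }, x0)
}

# scalar sum-of-squares node, used as a generic loss for gradient checks
sumSqNode <- function(nd) {
  out <- vesselStack:::vsNode(sum(nd$value^2) / 2)
  if (vesselStack:::vsTracing()) {
    out$backward <- function() vesselStack:::vsAcc(nd, out$grad * nd$value)
    vesselStack:::vsRecord(out)
  }
  out
}

# run a raw overfitting loop on one fixed batch; returns the loss trace
overfitBatch <- function(model, xb, yb, steps, lr = 1e-3, stop_at = NULL) {
  mod <- model@module
  opt <- vesselStack:::adamInit(mod$params, lr = lr)
  frozen <- vesselStack:::frozenMask(mod)
  old <- vesselStack:::vsSetTraining(TRUE)
  on.exit(vesselStack:::vsSetTraining(old))
  losses <- numeric(0)
  for (i in seq_len(steps)) {
    res <- vesselStack:::vsWithTape(
      vesselStack:::opBceLoss(mod$forward(vesselStack:::vsNode(xb)), yb))
    losses <- c(losses, res$value$value)
    if (!is.null(stop_at) && res$value$value <= stop_at) break
    vesselStack:::vsBackward(res$tape, res$value)
    if (any(frozen)) for (p in mod$params[frozen]) p$grad <- NULL
    vesselStack:::adamStep(mod$params, opt)
    vesselStack:::zeroGrads(mod$params)
  }
  losses
}

samplesToBatch <- function(samples) {
  d <- dim(samples[[1]]@image)
  xb <- array(0, c(d[1], d[2], 3, length(samples)))
  yb <- array(0, c(d[1], d[2], 1, length(samples)))
  for (k in seq_along(samples)) {
    xb[, , , k] <- samples[[k]]@image
    yb[, , 1, k] <- samples[[k]]@mask
  }
  list(x = xb, y = yb)
}
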