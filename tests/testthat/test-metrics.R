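# Metric formulas against hand-derived examples and independent oracles.

# naive per-pixel loop oracle for confusion counts
loopConfusion <- function(pred, truth, t) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] >= t) {
      if (truth[i] == 1) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (truth[i] == 1) fn <- fn + 1 else tn <- tn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# all-pairs Mann-Whitney oracle, O(P * N)
pairAuc <- function(pred, truth) {
  p <- pred[truth == 1]
  n <- pred[truth == 0]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("confusion counts match hand-enumerated examples", {
  cc <- confusionCounts(c(0.9, 0.2, 0.8, 0.6), c(1, 0, 0, 1), 0.5)
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(2, 1, 1, 0))
  # perfect prediction: no errors at any threshold
  y <- c(1, 0, 1, 1, 0)
  for (t in c(0.1, 0.5, 0.9)) {
    cc <- confusionCounts(y, y, t)
    expect_equal(cc@fp + cc@fn, 0)
  }
  # degenerate all-miss
  cc <- confusionCounts(rep(0, 7), rep(1, 7), 0.5)
  expect_equal(c(cc@fn, cc@tp, cc@fp, cc@tn), c(7, 0, 0, 0))
  expect_error(confusionCounts(1:4 / 5, c(1, 0)), "dimension mismatch")
})

test_that("ratio metrics follow the printed formulas", {
  cc <- new("ConfusionCounts", tp = 2, tn = 1, fp = 1, fn = 0)
  m <- ratioMetrics(cc)
  expect_equal(m$acc, 0.75)
  expect_equal(m$sn, 1.0)
  expect_equal(m$sp, 0.5)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f1, 0.8)
  # all-positive perfect case: specificity is 0/0, flagged and defined as 0
  m <- ratioMetrics(new("ConfusionCounts", tp = 9, tn = 0, fp = 0, fn = 0))
  expect_equal(c(m$acc, m$sn, m$f1), c(1, 1, 1))
  expect_equal(m$sp, 0)
  expect_true("sp" %in% attr(m, "flagged"))
  # swapping (tp<->tn, fp<->fn) swaps sn<->sp and fixes accuracy
  set.seed(8)
  for (i in 1:20) {
    k <- sample(0:50, 4, replace = TRUE)
    if (sum(k) == 0) next
    a <- ratioMetrics(new("ConfusionCounts", tp = k[1], tn = k[2],
                          fp = k[3], fn = k[4]))
    b <- ratioMetrics(new("ConfusionCounts", tp = k[2], tn = k[1],
                          fp = k[4], fn = k[3]))
    expect_equal(a$acc, b$acc)
    expect_equal(a$sn, b$sp)
    expect_equal(a$sp, b$sn)
  }
})

test_that("binary cross-entropy matches closed forms", {
  set.seed(9)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(bce(matrix(0.5, 8, 8), y), log(2), tolerance = 1e-9)
  expect_lte(bce(y, y), 1.3e-6)
  expect_equal(bce(0.9, 1), -log(0.9), tolerance = 1e-9)
})

test_that("AUC handles separation, ties and label swaps", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0)), 1.0)
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_error(rocAuc(c(0.1, 0.9), c(1, 1)), "undefined")
})

test_that("metrics agree with loop/all-pairs oracles on random maps", {
  set.seed(10)
  for (i in 1:25) {
    pred <- matrix(runif(32 * 32), 32, 32)
    truth <- matrix(rbinom(32 * 32, 1, runif(1, 0.05, 0.5)), 32, 32)
    t <- runif(1, 0.2, 0.8)
    cc <- confusionCounts(pred, truth, t)
    oc <- loopConfusion(pred, truth, t)
    expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn),
                     as.numeric(oc[c("tp", "tn", "fp", "fn")]))
    expect_equal(rocAuc(pred, truth), pairAuc(pred, truth), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(11)
  pred <- runif(500)
  truth <- rbinom(500, 1, 0.3)
  a0 <- rocAuc(pred, truth)
  for (f in list(function(x) x^3, function(x) exp(2 * x),
                 function(x) log(x + 1), function(x) 5 * x - 2)) {
    expect_equal(rocAuc(f(pred), truth), a0, tolerance = 1e-12)
  }
})

test_that("constant-predictor BCE is minimized at the foreground fraction", {
  set.seed(12)
  truth <- rbinom(400, 1, 0.23)
  frac <- mean(truth)
  grid <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(grid, function(p) bce(rep(p, 400), truth), numeric(1))
  expect_lte(abs(grid[which.min(losses)] - frac), 0.01)
})

test_that("accuracy is a step function changing only at observed predictions", {
  set.seed(13)
  pred <- round(runif(50), 2)
  truth <- rbinom(50, 1, 0.4)
  acc_at <- function(t) ratioMetrics(confusionCounts(pred, truth, t))$acc
  cuts <- sort(unique(pred))
  cuts <- cuts[cuts > 0 & cuts < 1]
  # between consecutive observed values accuracy is constant
  inner <- cuts[-length(cuts)] + diff(cuts) / 2
  for (i in seq_along(inner)) {
    lo <- acc_at(inner[i] - diff(cuts)[i] / 4)
    hi <- acc_at(inner[i] + diff(cuts)[i] / 4)
    expect_equal(acc_at(inner[i]), lo)
    expect_equal(hi, lo)
  }
})

test_that("model evaluation micro-averages pooled pixels", {
  s <- tinySamples(1, size = 16)[[1]]
  perfect <- s@mask
  r1 <- evaluateModel(list(perfect), list(s))
  expect_equal(c(r1@acc, r1@sn, r1@f1), c(1, 1, 1))
  expect_lte(r1@loss, 1e-5)
  # duplicating a sample (same prediction) leaves every ratio unchanged
  r2 <- evaluateModel(list(perfect, perfect), list(s, s))
  expect_equal(r2@acc, r1@acc)
  expect_equal(r2@sn, r1@sn)
  expect_equal(r2@f1, r1@f1)
  expect_equal(r2@nPixels, 2 * r1@nPixels)
  # report rows carry the Loss / Acc / SN / SP / AUC / F1 schema in order
  tab <- metricTable(list(model = r1))
  expect_identical(names(tab),
                   c("Model", "Loss", "Acc", "SN", "SP", "AUC", "F1-Score"))
})
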