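## Pixel-wise evaluation suite: confusion counts, ratio metrics, binary
## cross-entropy, rank-based AUC, and pooled (micro-averaged) reports.

#' Pixel-wise confusion counts
#'
#' A pixel counts as true positive when `pred >= threshold` and the truth is
#' 1, false positive when `pred >= threshold` and the truth is 0, false
#' negative when `pred < threshold` and the truth is 1, and true negative
#' otherwise.
#'
#' @param pred numeric array of vessel probabilities in `[0, 1]`.
#' @param truth binary array of the same shape.
#' @param threshold binarization threshold in (0, 1); default 0.5.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth, threshold = 0.5) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("dimension mismatch: pred and truth shapes differ")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  pos <- pred >= threshold
  t1 <- truth == 1
  new("ConfusionCounts",
      tp = as.numeric(sum(pos & t1)), fp = as.numeric(sum(pos & !t1)),
      fn = as.numeric(sum(!pos & t1)), tn = as.numeric(sum(!pos & !t1)))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Ratio metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 (harmonic mean of precision
#' and sensitivity).  Any 0/0 ratio is defined as 0 and listed in the
#' `flagged` attribute rather than returned as NaN.
#'
#' @param counts a [ConfusionCounts-class].
#' @return Named list `acc`, `sn`, `sp`, `precision`, `f1` with a
#'   `flagged` character attribute naming any 0/0 metrics.
#' @export
ratioMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty counts: no pixels evaluated")
  flagged <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  sn <- safe(tp, tp + fn, "sn")
  sp <- safe(tn, tn + fp, "sp")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * precision * sn, precision + sn, "f1")
  out <- list(acc = (tp + tn) / total, sn = sn, sp = sp,
              precision = precision, f1 = f1)
  attr(out, "flagged") <- flagged
  out
}

#' Pixel-wise binary cross-entropy
#'
#' `-(1/N) * sum(y * log(p) + (1-y) * log(1-p))` with probabilities clipped
#' to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred probability array.
#' @param truth binary array of the same shape.
#' @param eps clipping epsilon.
#' @return Non-negative scalar.
#' @export
bce <- function(pred, truth, eps = 1e-7) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("dimension mismatch: pred and truth shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Area under the ROC curve (rank statistic)
#'
#' The Mann-Whitney form: the probability that a random vessel pixel scores
#' higher than a random background pixel, ties counted one half.  Exactly
#' equivalent to trapezoidal ROC integration and invariant under strictly
#' increasing transforms of the scores.
#'
#' @param pred probability (or score) array.
#' @param truth binary array of the same shape; must contain both classes.
#' @param maxPixels if set, compute on a uniform pixel subsample of this
#'   size drawn with `seed` (for large pooled evaluations).
#' @param seed subsampling seed.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(pred, truth, maxPixels = NULL, seed = 1L) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("dimension mismatch: pred and truth shapes differ")
  p <- as.numeric(pred)
  y <- as.numeric(truth)
  if (!is.null(maxPixels) && length(p) > maxPixels) {
    idx <- withr::with_seed(seed, sample.int(length(p), maxPixels))
    p <- p[idx]
    y <- y[idx]
  }
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop("undefined metric: AUC needs both classes in the truth")
  r <- rank(p) # average ranks handle ties as 1/2
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a model (or precomputed maps) over a sample set
#'
#' Computes the report-table row for one model: loss, accuracy, sensitivity,
#' specificity, AUC and F1, micro-averaged over the pooled pixels of all
#' samples (counts are pooled before ratios are formed, the dominant
#' convention for the DRIVE/STARE benchmarks).
#'
#' @param model a [SegmentationModel-class], [MetaModel-class] plus base
#'   models (see [predictEnsemble()]), or a list of precomputed H x W
#'   probability matrices, one per sample.
#' @param samples non-empty list of [FundusSample-class] objects.
#' @param threshold binarization threshold for the count metrics.
#' @param aucMaxPixels optional pixel subsample size for the AUC term.
#' @return A [MetricReport-class].
#' @export
evaluateModel <- function(model, samples, threshold = 0.5, aucMaxPixels = NULL) {
  if (length(samples) == 0L) stop("samples must be non-empty")
  maps <- if (is.list(model) && !is(model, "SegmentationModel")) {
    stopifnot(length(model) == length(samples))
    model
  } else {
    lapply(samples, function(s) predict(model, s@image))
  }
  pred <- unlist(lapply(maps, as.numeric), use.names = FALSE)
  truth <- unlist(lapply(samples, function(s) as.numeric(s@mask)),
                  use.names = FALSE)
  reportFromPooled(pred, truth, threshold, aucMaxPixels)
}

reportFromPooled <- function(pred, truth, threshold, aucMaxPixels = NULL) {
  counts <- confusionCounts(pred, truth, threshold)
  rm_ <- ratioMetrics(counts)
  auc <- if (length(unique(truth)) < 2L) NA_real_ else
    rocAuc(pred, truth, maxPixels = aucMaxPixels)
  new("MetricReport", loss = bce(pred, truth), acc = rm_$acc, sn = rm_$sn,
      sp = rm_$sp, auc = auc, f1 = rm_$f1, precision = rm_$precision,
      threshold = threshold, nPixels = length(pred),
      flags = attr(rm_, "flagged"))
}

#' Format metric reports as a report table
#'
#' Assembles one row per model in the package's report schema
#' (Model, Loss, Acc, SN, SP, AUC, F1-Score).
#'
#' @param reports named list of [MetricReport-class] objects.
#' @return data.frame with one row per report.
#' @export
metricTable <- function(reports) {
  rows <- lapply(reports, as.data.frame)
  df <- do.call(rbind, rows)
  df <- cbind(Model = names(reports), df)
  names(df)[names(df) == "F1"] <- "F1-Score"
  rownames(df) <- NULL
  df
}
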