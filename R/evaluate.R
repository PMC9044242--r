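#' Rescale a probability map to an 8-bit gray segmentation map
#'
#' `round(p * 255)` per pixel (round-half-up), so the threshold search in
#' [selectThreshold()] operates on the integer range `[0, 255]` like a
#' gray image.
#'
#' @param probMap numeric matrix of probabilities in `[0, 1]`.
#' @return integer-valued matrix in `[0, 255]`.
#' @export
toGrayMap <- function(probMap) {
  if (any(probMap < 0 | probMap > 1)) stop("probabilities must lie in [0,1]")
  floor(probMap * 255 + 0.5)
}

#' Binarize a gray segmentation map at a global threshold
#'
#' @param grayMap integer-valued matrix in `[0, 255]`.
#' @param threshold integer in `[0, 255]`; pixels `>= threshold` become 1.
#' @return binary matrix.
#' @export
binarize <- function(grayMap, threshold) {
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0,255]")
  (grayMap >= threshold) * 1
}

#' Pooled FOV-restricted confusion counts
#'
#' Counts TP/TN/FP/FN over all supplied images, using only pixels inside
#' the field of view. Pixels outside the FOV never enter any metric.
#'
#' @param pred binary prediction matrix, or list of matrices.
#' @param label binary label matrix or list, matching `pred`.
#' @param fov binary FOV matrix or list, matching `pred`.
#' @return a [ConfusionCounts-class] object.
#' @export
confusionCounts <- function(pred, label, fov) {
  if (!is.list(pred)) { pred <- list(pred); label <- list(label); fov <- list(fov) }
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[[i]]; y <- label[[i]]; f <- fov[[i]]
    stopifNotBinary(p, "pred"); stopifNotBinary(y, "label")
    stopifNotBinary(f, "fov")
    if (!identical(dim(p), dim(y)) || !identical(dim(p), dim(f)))
      stop("pred, label and fov shapes must match")
    inside <- f == 1
    p <- p[inside]; y <- y[inside]
    tp <- tp + sum(p == 1 & y == 1)
    tn <- tn + sum(p == 0 & y == 0)
    fp <- fp + sum(p == 1 & y == 0)
    fn <- fn + sum(p == 0 & y == 1)
  }
  confusionFromCounts(tp, tn, fp, fn)
}

safeRatio <- function(num, den) if (den == 0) 0 else num / den

#' Threshold-level metrics from confusion counts
#'
#' Computes
#' \deqn{F1 = 2TP/(2TP+FP+FN),\ Se = TP/(TP+FN),\ Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/N,\ G = \sqrt{Se \cdot Sp},}
#' and the Matthews correlation coefficient. Sensitivity alone ignores
#' background and accuracy saturates under the ~1:9 vessel:background
#' imbalance of fundus images, so F1, G-mean and MCC are the balanced
#' headline metrics. Undefined ratios (zero denominators) are reported
#' as 0.
#'
#' @param counts a [ConfusionCounts-class] object.
#' @param mccVariant `"standard"` for the Matthews coefficient
#'   \eqn{(TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#'   `"as-printed"` for the non-negative variant
#'   \eqn{TP\cdot TN/\sqrt{(TP+TN)(TP+FN)(TN+FP)(TN+FN)}} found in parts
#'   of the vessel-segmentation literature.
#' @return a [MetricsReport-class] (with `auc` and `threshold` set to `NA`).
#' @examples
#' computeMetrics(confusionFromCounts(tp = 0, tn = 90, fp = 0, fn = 10))
#' @export
computeMetrics <- function(counts, mccVariant = c("standard", "as-printed")) {
  mccVariant <- match.arg(mccVariant)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("confusion counts are all zero")
  se <- safeRatio(tp, tp + fn)
  sp <- safeRatio(tn, tn + fp)
  f1 <- safeRatio(2 * tp, 2 * tp + fp + fn)
  acc <- (tp + tn) / n
  g <- sqrt(se * sp)
  mcc <- if (mccVariant == "standard") {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  } else {
    den <- sqrt(tp + tn) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn) / den
  }
  new("MetricsReport", acc = acc, se = se, sp = sp, f1 = f1, gmean = g,
      mcc = mcc, auc = NA_real_, threshold = NA_real_)
}

#' Rank-based AUC over pooled FOV pixels
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random vessel pixel scores higher than a random
#' background pixel, ties counted half. Invariant to strictly monotone
#' transforms of the scores.
#'
#' @param probMaps numeric score matrix or list of matrices.
#' @param labels,fovs matching binary matrices or lists.
#' @return AUC scalar in `[0, 1]`.
#' @export
computeAUC <- function(probMaps, labels, fovs) {
  if (!is.list(probMaps)) {
    probMaps <- list(probMaps); labels <- list(labels); fovs <- list(fovs)
  }
  scores <- numeric(0); truth <- numeric(0)
  for (i in seq_along(probMaps)) {
    inside <- fovs[[i]] == 1
    scores <- c(scores, probMaps[[i]][inside])
    truth <- c(truth, labels[[i]][inside])
  }
  nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
  if (nPos == 0 || nNeg == 0)
    stop("AUC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Select the optimal gray threshold by pooled F1
#'
#' Scans all thresholds `0..255`, computes the FOV-pooled F1 over the
#' validation maps at each, and returns the argmax; ties break toward the
#' lowest threshold.
#'
#' @param grayMaps gray segmentation map ([toGrayMap()]) or list thereof.
#' @param labels,fovs matching binary matrices or lists.
#' @return integer threshold in `[0, 255]`.
#' @export
selectThreshold <- function(grayMaps, labels, fovs) {
  if (!is.list(grayMaps)) {
    grayMaps <- list(grayMaps); labels <- list(labels); fovs <- list(fovs)
  }
  if (length(grayMaps) == 0) stop("need at least one validation image")
  g <- numeric(0); y <- numeric(0)
  for (i in seq_along(grayMaps)) {
    inside <- fovs[[i]] == 1
    g <- c(g, grayMaps[[i]][inside])
    y <- c(y, labels[[i]][inside])
  }
  # pooled F1 for every threshold t: pred = (g >= t).
  # cumulative counts over gray levels make the scan O(256 + n).
  nPos <- sum(y == 1)
  posHist <- tabulate(g[y == 1] + 1L, nbins = 256)
  negHist <- tabulate(g[y == 0] + 1L, nbins = 256)
  tpTail <- rev(cumsum(rev(posHist)))  # count of positives with g >= t
  fpTail <- rev(cumsum(rev(negHist)))
  f1 <- (2 * tpTail) / (2 * tpTail + fpTail + (nPos - tpTail))
  f1[!is.finite(f1)] <- 0
  which.max(f1) - 1L   # lowest threshold wins ties
}

#' Evaluate a trained model on test samples
#'
#' Runs the full inference path -- preprocessing, eval-mode forward pass,
#' unpadding -- over all test samples and reports the FOV-pooled metric
#' suite for the chosen output head at the given gray threshold, plus the
#' rank-based AUC of the continuous maps.
#'
#' @param model a trained model from [buildDbfuNet()] / [runStagedTraining()].
#' @param testSamples list of [FundusSample-class] objects.
#' @param threshold integer gray threshold fixed on validation data
#'   (see [selectThreshold()]); if `NULL` it is selected on `testSamples`
#'   themselves (only appropriate for validation data).
#' @param head `"fusion"`, `"decoder1"` or `"decoder2"`.
#' @param mccVariant passed to [computeMetrics()].
#' @return a [MetricsReport-class] with `auc` and `threshold` filled in.
#' @export
evaluateRun <- function(model, testSamples, threshold = NULL,
                        head = c("fusion", "decoder1", "decoder2"),
                        mccVariant = "standard") {
  head <- match.arg(head)
  if (length(testSamples) == 0) stop("empty test set")
  probs <- predictSamples(model, testSamples, head = head)
  labels <- lapply(testSamples, vesselLabel)
  fovs <- lapply(testSamples, fovMask)
  grays <- lapply(probs, toGrayMap)
  if (is.null(threshold)) threshold <- selectThreshold(grays, labels, fovs)
  preds <- lapply(grays, binarize, threshold = threshold)
  rep <- computeMetrics(confusionCounts(preds, labels, fovs),
                        mccVariant = mccVariant)
  rep@auc <- computeAUC(probs, labels, fovs)
  rep@threshold <- as.numeric(threshold)
  rep
}
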