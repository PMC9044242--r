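# Segmentation losses. All losses take predicted vessel probabilities and a
# binary target of the same shape, and reduce by the mean over pixels
# (dice, a set overlap, is inherently global). Probabilities are clipped to
# [epsClip, 1 - epsClip] before any log.

.EPS_CLIP <- 1e-7

lossValue <- function(value, nPixels) {
  structure(list(value = as.numeric(value), nPixels = as.integer(nPixels)),
            class = "lossValue")
}

#' @export
print.lossValue <- function(x, ...) {
  cat("loss", format(x$value), "over", x$nPixels, "pixels\n")
  invisible(x)
}

checkShapes <- function(pred, target, weights = NULL) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ")
  if (!is.null(weights) && length(weights) != length(pred))
    stop("weights shape differs from pred")
  invisible(TRUE)
}

#' Hard-example-weighted binary cross-entropy
#'
#' Cross-entropy per pixel, multiplied by the hard-example weight map
#' (see [hardWeightMap()]) and averaged:
#' \deqn{loss = -mean( [y \log\hat y + (1-y)\log(1-\hat y)] \cdot W_h ).}
#' Hard pixels (weight > 1) contribute proportionally more, steering the
#' optimizer toward vessel edges and thin vessels. With all weights 1 this
#' is plain binary cross-entropy.
#'
#' @param pred predicted probabilities in `[0, 1]`.
#' @param target binary labels, same shape.
#' @param weights weight map with values >= 1 (default all 1).
#' @param epsClip probability clipping bound guarding `log(0)`.
#' @return a `lossValue`: list with `value` (non-negative scalar) and
#'   `nPixels`.
#' @examples
#' weightedBCE(0.5, 1)$value            # ln 2
#' weightedBCE(0.5, 1, weights = 3)$value  # 3 ln 2
#' @export
weightedBCE <- function(pred, target, weights = NULL, epsClip = .EPS_CLIP) {
  checkShapes(pred, target, weights)
  if (is.null(weights)) weights <- rep(1, length(pred))
  if (any(weights < 1)) stop("weights must be >= 1")
  p <- clip01(pred, epsClip)
  ce <- -(target * log(p) + (1 - target) * log(1 - p))
  lossValue(mean(ce * weights), length(pred))
}

#' Plain binary cross-entropy
#'
#' @inheritParams weightedBCE
#' @return a `lossValue`.
#' @export
bceLoss <- function(pred, target, epsClip = .EPS_CLIP) {
  weightedBCE(pred, target, weights = NULL, epsClip = epsClip)
}

#' Focal loss
#'
#' \deqn{FL(p_t) = -(1 - p_t)^\gamma \log(p_t),\quad
#'       p_t = p \text{ if } y = 1, \text{ else } 1 - p,}
#' averaged over pixels. The modulating factor down-weights well-classified
#' pixels, so gradient mass concentrates on hard ones; `gamma = 0` recovers
#' cross-entropy. Default `gamma = 2`.
#'
#' @inheritParams weightedBCE
#' @param gamma focusing exponent >= 0.
#' @return a `lossValue`.
#' @export
focalLoss <- function(pred, target, gamma = 2, epsClip = .EPS_CLIP) {
  checkShapes(pred, target)
  if (length(gamma) != 1 || gamma < 0) stop("gamma must be >= 0")
  p <- clip01(pred, epsClip)
  pt <- ifelse(target == 1, p, 1 - p)
  lossValue(mean(-(1 - pt)^gamma * log(pt)), length(pred))
}

#' Dice loss
#'
#' \deqn{1 - \frac{2I + \epsilon}{U + \epsilon},\quad I = \sum t_i y_i,\quad
#'       U = \sum t_i + \sum y_i,}
#' a soft set-overlap loss robust to class imbalance. Default
#' `eps = 1e-5`.
#'
#' @inheritParams weightedBCE
#' @param eps positive smoothing constant.
#' @return a `lossValue`.
#' @export
diceLoss <- function(pred, target, eps = 1e-5) {
  checkShapes(pred, target)
  if (length(eps) != 1 || eps <= 0) stop("eps must be > 0")
  I <- sum(target * pred)
  U <- sum(target) + sum(pred)
  lossValue(1 - (2 * I + eps) / (U + eps), length(pred))
}
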