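#' Structuring elements for binary morphology
#'
#' Builds the symmetric footprint used by [binaryErode()] and
#' [binaryDilate()]. `square` is the full (2r+1) x (2r+1) block, `cross`
#' keeps the axis-aligned arms, `disk` keeps offsets within Euclidean
#' distance `radius` of the center.
#'
#' @param shape one of `"square"`, `"cross"`, `"disk"`.
#' @param radius integer radius >= 1; the footprint side is `2*radius + 1`.
#' @return binary matrix footprint, symmetric about its center.
#' @examples
#' structuringElement("cross", 1)
#' @export
structuringElement <- function(shape = c("square", "cross", "disk"),
                               radius = 1L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  k <- 2L * radius + 1L
  off <- seq.int(-radius, radius)
  dx <- matrix(off, k, k)
  dy <- t(dx)
  fp <- switch(shape,
    square = matrix(1, k, k),
    cross  = (dx == 0 | dy == 0) * 1,
    disk   = (dx^2 + dy^2 <= radius^2) * 1
  )
  structure(fp, shape = shape, radius = radius)
}

# shift a matrix by (dy, dx), filling vacated cells with `fill`
shiftMatrix <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# offsets (dy, dx) covered by a footprint
footprintOffsets <- function(se) {
  r <- (nrow(se) - 1L) / 2L
  idx <- which(se == 1, arr.ind = TRUE)
  cbind(dy = idx[, 1] - r - 1L, dx = idx[, 2] - r - 1L)
}

#' Binary erosion
#'
#' A pixel survives erosion iff the structuring element centered on it lies
#' entirely inside the foreground; pixels outside the image are treated as
#' background, so foreground touching the border erodes away.
#'
#' @param mask binary matrix.
#' @param se structuring element from [structuringElement()].
#' @return binary matrix of the same size.
#' @examples
#' m <- matrix(1, 5, 5)
#' binaryErode(m, structuringElement("square", 1))
#' @export
binaryErode <- function(mask, se = structuringElement("square", 1L)) {
  stopifNotBinary(mask, "mask")
  offs <- footprintOffsets(se)
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out * shiftMatrix(mask, -offs[i, 1], -offs[i, 2], fill = 0)
  out
}

#' Binary dilation
#'
#' A pixel is set iff the structuring element centered on it intersects the
#' foreground (out-of-image treated as background).
#'
#' @inheritParams binaryErode
#' @return binary matrix of the same size.
#' @export
binaryDilate <- function(mask, se = structuringElement("square", 1L)) {
  stopifNotBinary(mask, "mask")
  offs <- footprintOffsets(se)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- pmax(out, shiftMatrix(mask, -offs[i, 1], -offs[i, 2], fill = 0))
  out
}

#' Extract the hard-example mask from a vessel label by morphology
#'
#' Hard pixels -- thin vessels, vessel edges and the background band hugging
#' them -- are derived from the ground-truth label alone, without any rough
#' segmentation model, by the composition
#' \deqn{B = erode(L),\quad C = L \setminus B,\quad D = dilate(C),\quad
#'       Mask = D \setminus B,}
#' where `X \ Y` is the set difference `X & !Y`. `B` is the easy vessel
#' interior; `C` keeps vessel edges and whole thin vessels; dilating to `D`
#' adds the adjacent background band but re-introduces some interior
#' pixels, which the final subtraction of `B` removes again.
#'
#' @param label binary vessel label matrix.
#' @param seErode,seDilate structuring elements for the erosion and
#'   dilation steps (defaults: 3x3 square for both).
#' @return binary hard-example mask, same size as `label`.
#' @examples
#' L <- matrix(0, 9, 9); L[5, 2:8] <- 1  # a 1-px vessel
#' extractHardMask(L)
#' @export
extractHardMask <- function(label,
                            seErode = structuringElement("square", 1L),
                            seDilate = structuringElement("square", 1L)) {
  stopifNotBinary(label, "label")
  B <- binaryErode(label, seErode)
  C <- label * (1 - B)
  D <- binaryDilate(C, seDilate)
  D * (1 - B)
}

#' Per-pixel loss weight map from a hard-example mask
#'
#' `W = mask * weightHyper + 1`: easy pixels weigh 1, hard pixels weigh
#' `1 + weightHyper`. With `weightHyper = 0` the weighted cross-entropy
#' reduces to plain cross-entropy.
#'
#' @param mask binary hard-example mask (see [extractHardMask()]).
#' @param weightHyper non-negative scalar hyperparameter.
#' @return numeric matrix of weights, minimum value exactly 1.
#' @export
hardWeightMap <- function(mask, weightHyper = 2) {
  stopifNotBinary(mask, "mask")
  if (length(weightHyper) != 1 || weightHyper < 0)
    stop("weightHyper must be a single non-negative number")
  mask * weightHyper + 1
}

#' Hard-example mask from a probability band
#'
#' The reference extractor: pixels whose predicted vessel probability falls
#' in `[low, high]` (i.e. near 0.5, where the model is undecided) are
#' marked hard. Requires a rough segmentation model to produce `probMap`,
#' which is exactly what the morphology route ([extractHardMask()]) avoids.
#'
#' @param probMap numeric matrix of probabilities in `[0, 1]`.
#' @param low,high band limits, `0 <= low < high <= 1`.
#' @return binary mask, 1 where `low <= p <= high`.
#' @export
probabilityBandMask <- function(probMap, low = 0.4, high = 0.6) {
  if (any(probMap < 0 | probMap > 1)) stop("probMap must lie in [0, 1]")
  if (!(low >= 0 && high <= 1 && low < high))
    stop("band must satisfy 0 <= low < high <= 1")
  (probMap >= low & probMap <= high) * 1
}
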