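# Training-time geometric augmentation. Every transform is applied with
# one shared geometry to image, label and FOV; the image is interpolated
# bilinearly, label and FOV by nearest neighbor so they stay binary.
# Augmentation is strictly a training-time device -- the trainer never
# calls it in evaluation mode.

# sample coordinates (H x W matrices ys, xs) from planes with zero fill
sampleBilinear <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * get(y0, x0) +
       (1 - fy) * fx * get(y0, x0 + 1) +
       fy * (1 - fx) * get(y0 + 1, x0) +
       fy * fx * get(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

sampleNearest <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  yy <- round(ys); xx <- round(xs)
  ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
  v <- numeric(length(yy))
  v[ok] <- m[cbind(yy[ok], xx[ok])]
  matrix(v, H, W)
}

applyWarp <- function(sample, ys, xs) {
  img <- sampleImage(sample)
  out <- array(0, dim(img))
  for (ch in 1:3) out[, , ch] <- sampleBilinear(img[, , ch], ys, xs)
  lab <- sampleNearest(vesselLabel(sample), ys, xs)
  fov <- sampleNearest(fovMask(sample), ys, xs)
  fundusSample(round(out), lab * fov, fov, sampleId(sample))
}

#' Geometric augmentation: rotation, mirroring, translation
#'
#' Applies one random rigid transform -- rotation by an angle drawn from
#' `rotations`, optional horizontal mirror, and an integer translation up
#' to `translateMax` px -- identically to image, label and FOV. Regions
#' rotated in from outside the image are zero-filled; because the FOV is
#' transformed alongside, fill pixels never enter the metrics.
#'
#' @param sample a [FundusSample-class].
#' @param seed integer seed; the transform is deterministic given it.
#' @param rotations numeric vector of candidate angles in degrees
#'   (default `c(0, 90, 180, 270)` plus a uniform jitter of +-15 degrees
#'   when `jitter = TRUE`).
#' @param mirror allow horizontal mirroring.
#' @param translateMax maximum |translation| in px per axis.
#' @param jitter add continuous angular jitter to the drawn rotation.
#' @return the augmented [FundusSample-class].
#' @export
augmentGeometric <- function(sample, seed, rotations = c(0, 90, 180, 270),
                             mirror = TRUE, translateMax = 8L,
                             jitter = TRUE) {
  withSeed(seed, {
    ang <- base::sample(rotations, 1) + if (jitter) runif(1, -15, 15) else 0
    doMirror <- mirror && runif(1) < 0.5
    tr <- if (translateMax > 0)
      base::sample(seq.int(-translateMax, translateMax), 2, replace = TRUE)
      else c(0L, 0L)
    transformFundus(sample, angle = ang, mirror = doMirror, translate = tr)
  })
}

#' Deterministic rigid transform of a sample
#'
#' The deterministic core of [augmentGeometric()]: rotate by `angle`
#' degrees about the image center, optionally mirror horizontally, then
#' translate. Exposed separately so identity and involution properties
#' can be exercised directly.
#'
#' @param sample a [FundusSample-class].
#' @param angle rotation in degrees (counter-clockwise).
#' @param mirror logical, horizontal mirror.
#' @param translate integer `c(dy, dx)`.
#' @return transformed [FundusSample-class].
#' @export
transformFundus <- function(sample, angle = 0, mirror = FALSE,
                            translate = c(0L, 0L)) {
  H <- nrow(vesselLabel(sample)); W <- ncol(vesselLabel(sample))
  if (angle == 0 && !mirror && all(translate == 0)) return(sample)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse mapping: output pixel -> source location
  yy <- yy - translate[1]; xx <- xx - translate[2]
  th <- -angle * pi / 180
  ys <- cy + (yy * cos(th) - xx * sin(th))
  xs <- cx + (yy * sin(th) + xx * cos(th))
  if (mirror) xs <- 2 * cx - xs
  applyWarp(sample, ys, xs)
}

#' Random elastic deformation
#'
#' Simard-style elastic distortion: two independent uniform `[-1, 1]`
#' displacement fields are smoothed by a Gaussian of scale `sigma` px and
#' scaled to magnitude `alpha` px, then one and the same warped geometry
#' is applied to image (bilinear), label and FOV (nearest neighbor). This
#' enriches vessel morphology -- curvature, caliber variation -- beyond
#' what rigid transforms produce.
#'
#' @param sample a [FundusSample-class].
#' @param alpha displacement magnitude in px (>= 0; 0 is the identity).
#' @param sigma Gaussian smoothing scale in px (> 0); small sigma gives
#'   wiggly local distortion, large sigma a smooth global warp.
#' @param seed integer seed.
#' @return the deformed [FundusSample-class].
#' @export
elasticDeform <- function(sample, alpha = 34, sigma = 6, seed = 1L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha == 0) return(sample)
  H <- nrow(vesselLabel(sample)); W <- ncol(vesselLabel(sample))
  withSeed(seed, {
    dyf <- matrix(runif(H * W, -1, 1), H, W)
    dxf <- matrix(runif(H * W, -1, 1), H, W)
    dyf <- EBImage::imageData(EBImage::gblur(EBImage::Image(dyf), sigma))
    dxf <- EBImage::imageData(EBImage::gblur(EBImage::Image(dxf), sigma))
    # normalize each smoothed field so alpha is the peak displacement
    dyf <- alpha * dyf / max(abs(dyf), 1e-12)
    dxf <- alpha * dxf / max(abs(dxf), 1e-12)
    ys <- matrix(seq_len(H), H, W) + dyf
    xs <- matrix(seq_len(W), H, W, byrow = TRUE) + dxf
    applyWarp(sample, ys, xs)
  })
}
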