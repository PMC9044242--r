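#' Configuration for the synthetic fundus generator
#'
#' The generator emulates the statistical structure of DRIVE/STARE/CHASE
#' images that the segmentation method relies on: dark curvilinear
#' branching vessel trees (about 1-6 px wide, tapering toward the tips) on
#' a brighter textured background inside a circular field of view, a
#' bright optic-disc-like disk with a sharp edge (a classic false-positive
#' source), optional lesion-like blobs, and a vessel:background pixel
#' ratio near 1:9 inside the FOV.
#'
#' @param height,width image size in pixels (>= 64).
#' @param nTrees number of primary vessel trees rooted near the optic
#'   disc; `0` yields an empty label.
#' @param widthRange length-2 vessel width range in px (trunk to tip).
#' @param targetVesselFraction desired vessel fraction inside the FOV, in
#'   `(0, 0.5)`; the default 0.1 reproduces the ~1:9 class ratio of real
#'   fundus data.
#' @param discRadius optic disc radius in px; `0` suppresses the disc.
#' @param lesionCount number of lesion-like blobs.
#' @param noiseSd Gaussian pixel noise standard deviation (8-bit units).
#' @param seed integer RNG seed; every derived quantity is deterministic
#'   given it.
#' @return a `synthConfig` list.
#' @export
synthConfig <- function(height = 128L, width = 128L, nTrees = 3L,
                        widthRange = c(1L, 6L),
                        targetVesselFraction = 0.10,
                        discRadius = round(0.09 * min(height, width)),
                        lesionCount = 2L, noiseSd = 5, seed = 42L) {
  if (height < 64 || width < 64)
    stop("degenerate size: height and width must be >= 64")
  if (!(targetVesselFraction > 0 && targetVesselFraction < 0.5))
    stop("targetVesselFraction must lie in (0, 0.5)")
  if (widthRange[1] < 1 || widthRange[2] < widthRange[1])
    stop("widthRange must be increasing with min >= 1")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nTrees = as.integer(nTrees),
                 widthRange = as.numeric(widthRange),
                 targetVesselFraction = targetVesselFraction,
                 discRadius = as.numeric(discRadius),
                 lesionCount = as.integer(lesionCount),
                 noiseSd = as.numeric(noiseSd), seed = as.integer(seed)),
            class = "synthConfig")
}

# circular FOV mask and geometry shared by label and rendering
fovGeometry <- function(config) {
  H <- config$height; W <- config$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- 0.48 * min(H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- ((yy - cy)^2 + (xx - cx)^2 <= r^2) * 1
  list(fov = fov, cy = cy, cx = cx, r = r, yy = yy, xx = xx)
}

# stamp a disk of radius `rad` at (y, x) into mask (in place semantics via return)
stampDisk <- function(mask, y, x, rad) {
  H <- nrow(mask); W <- ncol(mask)
  y0 <- max(1, floor(y - rad)); y1 <- min(H, ceiling(y + rad))
  x0 <- max(1, floor(x - rad)); x1 <- min(W, ceiling(x + rad))
  if (y0 > y1 || x0 > x1) return(mask)
  ys <- y0:y1; xs <- x0:x1
  dy <- ys - y; dx <- xs - x
  patch <- outer(dy^2, dx^2, "+") <= rad^2
  mask[ys, xs] <- pmax(mask[ys, xs], patch * 1)
  mask
}

# trace one vessel branch as a perturbed walk, stamping tapered disks.
# Returns the updated label plus points visited (for spawning sub-branches).
traceBranch <- function(label, geom, y, x, angle, w0, w1, maxSteps) {
  pts <- matrix(NA_real_, maxSteps, 2)
  n <- 0
  for (s in seq_len(maxSteps)) {
    frac <- s / maxSteps
    w <- w0 + (w1 - w0) * frac            # taper trunk -> tip
    label <- stampDisk(label, y, x, w / 2)
    n <- n + 1
    pts[n, ] <- c(y, x)
    angle <- angle + rnorm(1, 0, 0.18)    # smooth curvature
    # per-axis step < 1 px so rounding cannot open gaps in 1-px tips
    y <- y + 0.95 * sin(angle)
    x <- x + 0.95 * cos(angle)
    inside <- (y - geom$cy)^2 + (x - geom$cx)^2 <= (geom$r - 1)^2
    if (!inside) break
  }
  list(label = label, pts = pts[seq_len(n), , drop = FALSE])
}

#' Generate a synthetic branching vessel-tree label
#'
#' Draws `nTrees` random-walk vessel trees rooted near the optic-disc
#' position, with stochastic bifurcation and widths tapering from the top
#' of `widthRange` at the trunk to ~1 px at the tips, rasterized with
#' disk-shaped brushes and clipped to the circular FOV. Additional
#' branches are grown from existing vessel points until the vessel
#' fraction inside the FOV reaches `targetVesselFraction` (or a growth
#' cap), making the realized class ratio track the target.
#'
#' @param config a [synthConfig()].
#' @return binary `H x W` label matrix.
#' @examples
#' L <- generateVesselTree(synthConfig(seed = 7))
#' mean(L[fovGeometryMask(synthConfig(seed = 7)) == 1])
#' @export
generateVesselTree <- function(config) {
  geom <- fovGeometry(config)
  H <- config$height; W <- config$width
  label <- matrix(0, H, W)
  if (config$nTrees < 1) return(label)
  withSeed(deriveSeed(config$seed, 1L), {
    wmax <- config$widthRange[2]; wmin <- config$widthRange[1]
    scale <- min(H, W)
    # disc sits off-center; trees start near it and grow outward
    discAng <- runif(1, 0, 2 * pi)
    rootY <- geom$cy + 0.55 * geom$r * sin(discAng)
    rootX <- geom$cx + 0.55 * geom$r * cos(discAng)
    allPts <- NULL
    grow <- function(label, y, x, ang, w0, depth) {
      res <- traceBranch(label, geom, y, x, ang, w0,
                         max(wmin, w0 * 0.4),
                         maxSteps = round(scale * runif(1, 0.25, 0.6)))
      label <- res$label
      allPts <<- rbind(allPts, res$pts)
      if (depth < 3 && nrow(res$pts) > 4) {
        nKids <- rpois(1, 1.2)
        for (k in seq_len(nKids)) {
          at <- res$pts[sample(nrow(res$pts), 1), ]
          label <- grow(label, at[1], at[2],
                        ang + runif(1, -1.2, 1.2) * sample(c(-1, 1), 1),
                        max(wmin, w0 * runif(1, 0.5, 0.8)), depth + 1)
        }
      }
      label
    }
    for (t in seq_len(config$nTrees)) {
      ang <- discAng + pi + runif(1, -1.5, 1.5)  # grow away from the disc
      label <- grow(label, rootY + runif(1, -3, 3), rootX + runif(1, -3, 3),
                    ang, runif(1, 0.8, 1) * wmax, 1)
    }
    # top up toward the target class ratio with thin secondary branches
    nFov <- sum(geom$fov)
    for (it in seq_len(60)) {
      frac <- sum(label * geom$fov) / nFov
      if (frac >= config$targetVesselFraction) break
      at <- allPts[sample(nrow(allPts), 1), ]
      res <- traceBranch(label, geom, at[1], at[2], runif(1, 0, 2 * pi),
                         runif(1, wmin, 0.5 * wmax), wmin,
                         maxSteps = round(scale * runif(1, 0.2, 0.45)))
      label <- res$label
      allPts <- rbind(allPts, res$pts)
    }
    label * geom$fov
  })
}

#' FOV mask implied by a generator configuration
#' @param config a [synthConfig()].
#' @return binary `H x W` FOV matrix.
#' @export
fovGeometryMask <- function(config) fovGeometry(config)$fov

#' Render a fundus-like image for a vessel label
#'
#' Builds an RGB image in which vessels are darker than the background in
#' the green channel, the background carries a smooth illumination
#' gradient plus Gaussian noise, one bright optic-disc-like disk with a
#' sharp edge sits at the tree root, `lesionCount` bright/dark blobs mimic
#' pathology, and everything outside the circular FOV is near-black.
#'
#' @param label binary `H x W` vessel label (as from
#'   [generateVesselTree()]).
#' @param config the same [synthConfig()] used for the label.
#' @return a [FundusSample-class].
#' @export
renderFundus <- function(label, config) {
  stopifNotBinary(label, "label")
  if (!all(dim(label) == c(config$height, config$width)))
    stop("label shape does not match config")
  geom <- fovGeometry(config)
  H <- config$height; W <- config$width
  withSeed(deriveSeed(config$seed, 2L), {
    # smooth illumination field: low-frequency sinusoidal modulation
    phy <- runif(2, 0, 2 * pi); frq <- runif(2, 0.7, 1.6)
    field <- 1 + 0.10 * sin(frq[1] * pi * geom$yy / H + phy[1]) *
                    cos(frq[2] * pi * geom$xx / W + phy[2])
    green <- 150 * field
    green[label == 1] <- (150 - 65) * field[label == 1]  # vessels darker
    # optic disc: bright, sharp-edged, at the vessel root position
    discAng <- withSeed(deriveSeed(config$seed, 1L), runif(1, 0, 2 * pi))
    if (config$discRadius > 0) {
      dy <- geom$yy - (geom$cy + 0.55 * geom$r * sin(discAng))
      dx <- geom$xx - (geom$cx + 0.55 * geom$r * cos(discAng))
      disc <- (dy^2 + dx^2 <= config$discRadius^2)
      green[disc] <- pmin(250, green[disc] + 70)
    }
    # lesion-like blobs (soft gaussian bumps, bright or dark)
    for (l in seq_len(config$lesionCount)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0.2, 0.8) * geom$r
      ly <- geom$cy + rad * sin(ang); lx <- geom$cx + rad * cos(ang)
      sz <- runif(1, 2, 5); amp <- sample(c(-1, 1), 1) * runif(1, 20, 40)
      bump <- amp * exp(-((geom$yy - ly)^2 + (geom$xx - lx)^2) / (2 * sz^2))
      green <- green + bump
    }
    if (config$noiseSd > 0)
      green <- green + rnorm(H * W, 0, config$noiseSd)
    green <- pmin(pmax(green, 0), 255)
    red <- pmin(pmax(green * 1.25 + 30, 0), 255)
    blue <- pmin(pmax(green * 0.45, 0), 255)
    img <- array(0, c(H, W, 3))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    outside <- geom$fov == 0
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[outside] <- 2; img[, , ch] <- pl
    }
    img <- round(img)
    fundusSample(img, label * geom$fov, geom$fov,
                 sprintf("synth_seed%d", config$seed))
  })
}

#' Generate a reproducible synthetic fundus dataset
#'
#' Produces `n` samples with per-sample seeds derived from the master
#' `config$seed`, so sample `i` is identical regardless of `n`.
#'
#' @param n number of samples >= 1.
#' @param config master [synthConfig()].
#' @return list of [FundusSample-class] objects with distinct ids.
#' @export
generateFundusDataset <- function(n, config = synthConfig()) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    ci <- config
    ci$seed <- as.integer(deriveSeed(config$seed, i, stream = 5L))
    s <- renderFundus(generateVesselTree(ci), ci)
    s@sampleId <- sprintf("synth_%03d", i)
    s
  })
}
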