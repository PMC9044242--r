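#' Extract the green channel of an RGB fundus image
#'
#' Retinal vessels show the highest contrast against the background in the
#' green channel, so the network consumes it as a single-channel input.
#'
#' @param image numeric `H x W x 3` array (channel order R, G, B).
#' @return `H x W` matrix, the green channel unchanged.
#' @export
extractGreen <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("image must have exactly 3 channels (R, G, B)")
  image[, , 2]
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Local contrast enhancement on the 8-bit green channel before network
#' input. Deterministic for fixed parameters.
#'
#' @param gray `H x W` matrix of 8-bit intensities in `[0, 255]`.
#' @param clipLimit positive contrast clip limit (default 2).
#' @param tileGrid length-2 integer vector, tiles along (rows, cols)
#'   (default `c(8, 8)`).
#' @return `H x W` matrix of 8-bit intensities in `[0, 255]`.
#' @export
claheEnhance <- function(gray, clipLimit = 2, tileGrid = c(8L, 8L)) {
  if (clipLimit <= 0) stop("clipLimit must be positive")
  if (any(gray < 0 | gray > 255)) stop("gray values must lie in [0, 255]")
  if (max(gray) == min(gray)) return(gray)  # no contrast to redistribute
  out <- EBImage::clahe(EBImage::Image(gray / 255),
                        nx = tileGrid[2], ny = tileGrid[1],
                        limit = clipLimit)
  m <- EBImage::imageData(out)
  pmin(pmax(round(m * 255), 0), 255)
}

#' Pad sample arrays so each side is divisible by a power-of-two multiple
#'
#' The network downsamples by a factor `2^depth`, so input sides must be
#' divisible by that multiple (32 for the default depth 5). Padding is
#' zero-fill on the bottom and right; the label and FOV are padded with
#' zeros too, so padded pixels carry no vessels and are automatically
#' excluded from FOV-restricted metrics.
#'
#' @param arrays a single matrix or a named list of matrices sharing one
#'   size (e.g. `list(data = ..., label = ..., fov = ...)`).
#' @param multiple integer >= 1 (default 32).
#' @return list with `data` (the padded matrix or list), `padOffsets`
#'   (`c(top, bottom, left, right)`) and `originalSize` (`c(H, W)`).
#' @export
padToMultiple <- function(arrays, multiple = 32L) {
  single <- !is.list(arrays)
  if (single) arrays <- list(arrays)
  H <- nrow(arrays[[1]]); W <- ncol(arrays[[1]])
  Hp <- as.integer(ceiling(H / multiple) * multiple)
  Wp <- as.integer(ceiling(W / multiple) * multiple)
  padded <- lapply(arrays, function(m) {
    out <- matrix(0, Hp, Wp)
    out[seq_len(H), seq_len(W)] <- m
    out
  })
  list(data = if (single) padded[[1]] else padded,
       padOffsets = c(top = 0L, bottom = Hp - H, left = 0L, right = Wp - W),
       originalSize = c(H, W))
}

#' Remove padding from an output map
#'
#' Exact inverse of [padToMultiple()].
#'
#' @param map padded matrix.
#' @param padOffsets `c(top, bottom, left, right)` as recorded by
#'   [padToMultiple()].
#' @param originalSize `c(H, W)` before padding.
#' @return the unpadded `H x W` matrix.
#' @export
cropToOriginal <- function(map, padOffsets, originalSize) {
  H <- originalSize[1]; W <- originalSize[2]
  if (nrow(map) != H + padOffsets[1] + padOffsets[2] ||
      ncol(map) != W + padOffsets[3] + padOffsets[4])
    stop("map size inconsistent with padOffsets + originalSize")
  map[padOffsets[1] + seq_len(H), padOffsets[3] + seq_len(W), drop = FALSE]
}

#' Full preprocessing of a FundusSample into a network-ready input
#'
#' green channel -> CLAHE -> rescale to `[0, 1]` -> pad to a multiple of
#' `2^depth`, with label and FOV padded alongside.
#'
#' @param sample a [FundusSample-class].
#' @param claheClip,claheTiles CLAHE parameters (see [claheEnhance()]).
#' @param padMultiple padding multiple (32 for the full-depth network).
#' @return list with `input` (padded `[0,1]` matrix), `label`, `fov`
#'   (padded binaries), `padOffsets`, `originalSize`.
#' @export
preprocessSample <- function(sample, claheClip = 2, claheTiles = c(8L, 8L),
                             padMultiple = 32L) {
  g <- claheEnhance(extractGreen(sampleImage(sample)),
                    clipLimit = claheClip, tileGrid = claheTiles)
  p <- padToMultiple(list(data = g / 255, label = vesselLabel(sample),
                          fov = fovMask(sample)),
                     multiple = padMultiple)
  list(input = p$data$data, label = p$data$label, fov = p$data$fov,
       padOffsets = p$padOffsets, originalSize = p$originalSize)
}
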