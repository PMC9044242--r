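#' Random channel attention (RCA) parameters
#'
#' RCA regularizes training by multiplying every feature channel by a
#' freshly sampled random weight; at inference it is the identity. Unlike
#' learned (squeeze-and-excitation) channel attention the weights carry no
#' information -- their randomness is the point, analogous to dropout but
#' soft: channels are rescaled, never zeroed outright.
#'
#' Weights are drawn from a Gaussian with the given mean and variance and
#' clipped to `clip` (symmetric about the mean, so the post-clip mean stays
#' at `mean` and negative sign-flipping weights are excluded).
#'
#' @param mean weight mean (default 1, so features are unbiased on average
#'   and inference needs no rescaling).
#' @param variance weight variance >= 0 (default 0.5).
#' @param clip length-2 clipping range, symmetric about `mean`.
#' @param distribution distribution family; `"gaussian"` is the only
#'   built-in.
#' @return an `rcaParams` list.
#' @export
rcaParams <- function(mean = 1, variance = 0.5, clip = c(0, 2),
                      distribution = "gaussian") {
  if (variance < 0) stop("variance must be >= 0")
  if (length(clip) != 2 || clip[1] > clip[2])
    stop("clip must be an increasing length-2 range")
  if (abs((clip[1] + clip[2]) / 2 - mean) > 1e-9)
    stop("clip range must be symmetric about the mean")
  distribution <- match.arg(distribution, "gaussian")
  structure(list(mean = mean, variance = variance, clip = clip,
                 distribution = distribution),
            class = "rcaParams")
}

#' Sample per-channel RCA weights
#'
#' Draws one weight per channel from the configured distribution, then
#' clips. Uses the global RNG stream, so results are deterministic given
#' the RNG state (e.g. after `set.seed()`).
#'
#' @param nChannels number of channels >= 1.
#' @param params an [rcaParams()] object.
#' @param clip if `FALSE`, return the raw (pre-clip) draws; useful for
#'   inspecting the distribution's moments.
#' @return numeric vector of length `nChannels`.
#' @examples
#' set.seed(1)
#' sampleChannelWeights(4, rcaParams())
#' @export
sampleChannelWeights <- function(nChannels, params = rcaParams(),
                                 clip = TRUE) {
  if (nChannels < 1) stop("nChannels must be >= 1")
  w <- rnorm(nChannels, mean = params$mean, sd = sqrt(params$variance))
  if (clip) w <- pmin(pmax(w, params$clip[1]), params$clip[2])
  w
}

#' Apply random channel attention to a feature block
#'
#' In `"train"` mode each channel of the block is multiplied by its own
#' freshly sampled random weight (broadcast over all spatial positions);
#' in `"eval"` mode the block is returned unchanged. Because the weight
#' mean is 1, no inference-time rescaling is needed.
#'
#' @param featureBlock numeric array `H x W x C`, or a matrix `(H*W) x C`.
#' @param params an [rcaParams()] object.
#' @param mode `"train"` or `"eval"`.
#' @param weights optional fixed weight vector overriding sampling (used
#'   for testing and by the backward pass).
#' @return object of the same shape as `featureBlock`.
#' @export
applyRCA <- function(featureBlock, params = rcaParams(),
                     mode = c("train", "eval"), weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "eval") return(featureBlock)
  d <- dim(featureBlock)
  nc <- d[length(d)]
  if (is.null(weights)) weights <- sampleChannelWeights(nc, params)
  if (length(weights) != nc) stop("weights length must match channel count")
  if (length(d) == 3) {
    out <- featureBlock * rep(weights, each = d[1] * d[2])
  } else {
    out <- featureBlock * rep(weights, each = d[1])
  }
  attr(out, "rcaWeights") <- weights
  out
}
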