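#' Model specification for the double-branch fusion U-Net
#'
#' The network has four named parameter groups: a shared `encoder`
#' (`depth` residual downsampling stages plus a bottleneck), two
#' structurally identical decoders (`decoder1`, `decoder2`) that both
#' receive additive skip connections from every encoder stage, and a
#' `fusion` group that concatenates the two decoders' final feature maps,
#' passes them through one residual block and a 1x1 convolution to produce
#' the final probability map. Every residual block contains a random
#' channel attention step (see [rcaParams()]). Channel width doubles at
#' each downsampling stage starting from `baseChannels`.
#'
#' @param depth number of downsampling stages (default 5; input sides must
#'   be divisible by `2^depth`).
#' @param baseChannels channels at the first stage (default 16).
#' @param rca an [rcaParams()] object; set `variance = 0` to disable RCA.
#' @param init weight initialization scheme; `"he-normal"` is the only
#'   built-in.
#' @param singleBranch if `TRUE`, build the single-branch ablation variant
#'   (encoder + decoder1 only, no fusion).
#' @return a `modelSpec` list.
#' @export
modelSpec <- function(depth = 5L, baseChannels = 16L, rca = rcaParams(),
                      init = "he-normal", singleBranch = FALSE) {
  if (depth < 1) stop("depth must be >= 1")
  if (baseChannels < 1) stop("baseChannels must be >= 1")
  init <- match.arg(init, "he-normal")
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 rca = rca, init = init,
                 singleBranch = isTRUE(singleBranch)),
            class = "modelSpec")
}

initEncoder <- function(spec) {
  c0 <- spec$baseChannels
  enc <- list(stem = newUnit(3L, 1L, c0))
  for (i in seq_len(spec$depth)) {
    ci <- c0 * 2^(i - 1)
    enc[[paste0("res", i)]] <- newRes(ci, ci)
    enc[[paste0("down", i)]] <- newUnit(3L, ci, 2L * ci, stride = 2L)
  }
  cb <- c0 * 2^spec$depth
  enc$bottleneck <- newRes(cb, cb)
  enc
}

initDecoder <- function(spec) {
  c0 <- spec$baseChannels
  dec <- list()
  for (i in seq_len(spec$depth)) {
    ci <- c0 * 2^(i - 1)
    dec[[paste0("up", i)]] <- newUnit(3L, 2L * ci, ci)
    dec[[paste0("res", i)]] <- newRes(ci, ci)
  }
  dec$head <- newConv(1L, c0, 1L)
  dec
}

initFusion <- function(spec) {
  c0 <- spec$baseChannels
  list(res = newRes(2L * c0, c0), out = newConv(1L, c0, 1L))
}

#' Build a double-branch fusion U-Net
#'
#' Instantiates all parameter groups with he-normal initialization under
#' the given seed; two builds with the same spec and seed are identical.
#'
#' @param spec a [modelSpec()].
#' @param seed integer RNG seed for initialization.
#' @return a model list with elements `spec`, `params` (nested parameter
#'   groups `encoder`, `decoder1`, `decoder2`, `fusion`), and `seed`.
#' @export
buildDbfuNet <- function(spec = modelSpec(), seed = 1L) {
  params <- withSeed(seed, {
    p <- list(encoder = initEncoder(spec), decoder1 = initDecoder(spec))
    if (!spec$singleBranch) {
      p$decoder2 <- initDecoder(spec)
      p$fusion <- initFusion(spec)
    }
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "dbfuNet")
}

#' @export
print.dbfuNet <- function(x, ...) {
  cat("Double-branch fusion U-Net: depth", x$spec$depth,
      "base channels", x$spec$baseChannels,
      if (x$spec$singleBranch) "(single branch)" else "", "\n")
  cat("  parameters:", parameterCount(x), "\n")
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a model from [buildDbfuNet()].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  n <- 0
  walk <- function(p) {
    for (nm in c("W", "b", "gamma", "beta"))
      if (!is.null(p[[nm]])) n <<- n + length(p[[nm]])
    for (el in p) if (is.list(el)) walk(el)
  }
  walk(model$params)
  n
}

# --- full network forward / backward ---------------------------------------

encoderFwd <- function(enc, x, H, W, rca, mode) {
  caches <- list(); skips <- list(); dims <- list()
  st <- unitFwd(enc$stem, x, H, W); caches$stem <- st
  f <- st$out; h <- H; w <- W
  depth <- (length(enc) - 2L) / 2L
  for (i in seq_len(depth)) {
    rs <- resFwd(enc[[paste0("res", i)]], f, h, w, rca, mode)
    caches[[paste0("res", i)]] <- rs
    skips[[i]] <- rs$out; dims[[i]] <- c(h, w)
    dn <- unitFwd(enc[[paste0("down", i)]], rs$out, h, w)
    caches[[paste0("down", i)]] <- dn
    f <- dn$out; h <- dn$H; w <- dn$W
  }
  bt <- resFwd(enc$bottleneck, f, h, w, rca, mode)
  caches$bottleneck <- bt
  list(out = bt$out, H = h, W = w, skips = skips, dims = dims,
       caches = caches, depth = depth)
}

encoderBwd <- function(enc, ec, dBott, dSkips) {
  grads <- list()
  bb <- resBwd(enc$bottleneck, ec$caches$bottleneck$cache, dBott)
  grads$bottleneck <- bb$grads
  d <- bb$dx
  for (i in rev(seq_len(ec$depth))) {
    db <- unitBwd(enc[[paste0("down", i)]],
                  ec$caches[[paste0("down", i)]]$cache, d)
    grads[[paste0("down", i)]] <- db$grads
    d <- db$dx + dSkips[[i]]
    rb <- resBwd(enc[[paste0("res", i)]],
                 ec$caches[[paste0("res", i)]]$cache, d)
    grads[[paste0("res", i)]] <- rb$grads
    d <- rb$dx
  }
  sb <- unitBwd(enc$stem, ec$caches$stem$cache, d)
  grads$stem <- sb$grads
  list(grads = grads, dx = sb$dx)
}

decoderFwd <- function(dec, ec, rca, mode) {
  caches <- list()
  f <- ec$out; h <- ec$H; w <- ec$W
  for (i in rev(seq_len(ec$depth))) {
    up <- upsampleFwd(f, h, w)
    h <- 2L * h; w <- 2L * w
    uc <- unitFwd(dec[[paste0("up", i)]], up$out, h, w)
    fa <- uc$out + ec$skips[[i]]
    rs <- resFwd(dec[[paste0("res", i)]], fa, h, w, rca, mode)
    caches[[paste0("lev", i)]] <- list(upIdx = up$idx, uc = uc, rs = rs)
    f <- rs$out
  }
  hd <- convFwd(dec$head, f, h, w)
  caches$head <- hd
  list(feat = f, z = hd$out, H = h, W = w, caches = caches)
}

# dFeat: gradient at the decoder's final feature map (from fusion), may be
# NULL; dz: gradient at the head logits, may be NULL.
decoderBwd <- function(dec, dc, ec, dFeat, dz) {
  grads <- list(); depth <- ec$depth
  d <- if (is.null(dFeat)) 0 else dFeat
  if (!is.null(dz)) {
    hb <- convBwd(dec$head, dc$caches$head$cache, dz)
    grads$head <- list(W = hb$dW, b = hb$db)
    d <- d + hb$dx
  } else {
    grads$head <- list(W = dec$head$W * 0, b = dec$head$b * 0)
  }
  dSkips <- vector("list", depth)
  for (i in seq_len(depth)) {
    lv <- dc$caches[[paste0("lev", i)]]
    rb <- resBwd(dec[[paste0("res", i)]], lv$rs$cache, d)
    grads[[paste0("res", i)]] <- rb$grads
    dSkips[[i]] <- rb$dx            # additive skip: same gradient
    ub <- unitBwd(dec[[paste0("up", i)]], lv$uc$cache, rb$dx)
    grads[[paste0("up", i)]] <- ub$grads
    d <- upsampleBwd(lv$upIdx, ub$dx)
  }
  list(grads = grads, dBott = d, dSkips = dSkips)
}

fusionFwd <- function(fus, f1, f2, H, W, rca, mode) {
  cc <- cbind(f1, f2)
  rs <- resFwd(fus$res, cc, H, W, rca, mode)
  out <- convFwd(fus$out, rs$out, H, W)
  list(z = out$out, caches = list(rs = rs, out = out, c1 = ncol(f1)))
}

fusionBwd <- function(fus, fc, dz) {
  ob <- convBwd(fus$out, fc$caches$out$cache, dz)
  rb <- resBwd(fus$res, fc$caches$rs$cache, ob$dx)
  c1 <- fc$caches$c1
  list(grads = list(res = rb$grads, out = list(W = ob$dW, b = ob$db)),
       dF1 = rb$dx[, seq_len(c1), drop = FALSE],
       dF2 = rb$dx[, c1 + seq_len(ncol(rb$dx) - c1), drop = FALSE])
}

checkGeometry <- function(model, H, W) {
  m <- 2^model$spec$depth
  if (H %% m != 0 || W %% m != 0)
    stop("input sides (", H, " x ", W, ") must be divisible by 2^depth = ", m)
}

# forward pass returning probabilities and (optionally) all caches.
# branches: which parts to compute ("d1", "d2", "fusion"); fusion forces
# both decoders.
dbfuForwardFull <- function(model, input, mode, withCache = FALSE,
                            branches = c("d1", "d2", "fusion")) {
  H <- nrow(input); W <- ncol(input)
  checkGeometry(model, H, W)
  p <- model$params; rca <- model$spec$rca
  if (model$spec$singleBranch) branches <- "d1"
  if ("fusion" %in% branches) branches <- c("d1", "d2", "fusion")
  x <- matrix(as.numeric(input), H * W, 1L)
  ec <- encoderFwd(p$encoder, x, H, W, rca, mode)
  res <- list()
  d1 <- d2 <- fu <- NULL
  if ("d1" %in% branches) {
    d1 <- decoderFwd(p$decoder1, ec, rca, mode)
    res$z1 <- d1$z; res$p1 <- matrix(sigmoidStable(d1$z), H, W)
  }
  if ("d2" %in% branches) {
    d2 <- decoderFwd(p$decoder2, ec, rca, mode)
    res$z2 <- d2$z; res$p2 <- matrix(sigmoidStable(d2$z), H, W)
  }
  if ("fusion" %in% branches) {
    fu <- fusionFwd(p$fusion, d1$feat, d2$feat, H, W, rca, mode)
    res$zf <- fu$z; res$pf <- matrix(sigmoidStable(fu$z), H, W)
  }
  if (withCache) res$cache <- list(ec = ec, d1 = d1, d2 = d2, fu = fu)
  res
}

#' Run the network forward on a padded single-channel input
#'
#' @param model a model from [buildDbfuNet()].
#' @param input `H x W` matrix in `[0, 1]`, sides divisible by
#'   `2^depth`.
#' @param mode `"train"` (RCA active, stochastic) or `"eval"`
#'   (deterministic identity RCA).
#' @return list of probability maps `p1`, `p2`, `pf` (the latter two
#'   `NULL` for a single-branch model), each `H x W` in `[0, 1]`.
#' @export
netForward <- function(model, input, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  out <- dbfuForwardFull(model, input, mode)
  list(p1 = out$p1, p2 = out$p2, pf = out$pf)
}

# backward pass: head logit gradients (any may be NULL) -> parameter
# grads. Only groups named in `groups` (plus those upstream gradients
# require) are traversed; everything else receives zero gradients, so
# frozen-phase steps skip most of the graph.
dbfuBackward <- function(model, fw, dz1 = NULL, dz2 = NULL, dzf = NULL,
                         groups = c("encoder", "decoder1", "decoder2",
                                    "fusion")) {
  p <- model$params; ca <- fw$cache
  single <- model$spec$singleBranch
  needEnc <- "encoder" %in% groups
  grads <- list()
  dF1 <- dF2 <- NULL
  if (!single) {
    if (!is.null(dzf) &&
        any(c("fusion", "decoder1", "decoder2", "encoder") %in% groups)) {
      fb <- fusionBwd(p$fusion, ca$fu, dzf)
      grads$fusion <- if ("fusion" %in% groups) fb$grads
                      else zeroLike(p$fusion)
      if (any(c("decoder1", "decoder2", "encoder") %in% groups)) {
        dF1 <- fb$dF1; dF2 <- fb$dF2
      }
    } else {
      grads$fusion <- zeroLike(p$fusion)
    }
  }
  dBott <- NULL; dSkips <- NULL
  if ((!is.null(dz1) || !is.null(dF1)) &&
      ("decoder1" %in% groups || needEnc)) {
    b1 <- decoderBwd(p$decoder1, ca$d1, ca$ec, dF1, dz1)
    grads$decoder1 <- if ("decoder1" %in% groups) b1$grads
                      else zeroLike(p$decoder1)
    dBott <- b1$dBott; dSkips <- b1$dSkips
  } else {
    grads$decoder1 <- zeroLike(p$decoder1)
  }
  if (!single && (!is.null(dz2) || !is.null(dF2)) &&
      ("decoder2" %in% groups || needEnc)) {
    b2 <- decoderBwd(p$decoder2, ca$d2, ca$ec, dF2, dz2)
    grads$decoder2 <- if ("decoder2" %in% groups) b2$grads
                      else zeroLike(p$decoder2)
    if (is.null(dBott)) {
      dBott <- b2$dBott; dSkips <- b2$dSkips
    } else {
      dBott <- dBott + b2$dBott
      for (i in seq_along(dSkips))
        dSkips[[i]] <- dSkips[[i]] + b2$dSkips[[i]]
    }
  } else if (!single) {
    grads$decoder2 <- zeroLike(p$decoder2)
  }
  if (needEnc) {
    if (is.null(dBott)) stop("no gradient reaches the encoder")
    eb <- encoderBwd(p$encoder, ca$ec, dBott, dSkips)
    grads$encoder <- eb$grads
  } else {
    grads$encoder <- zeroLike(p$encoder)
  }
  grads
}

# nested structure of zeros matching a parameter (sub)tree
zeroLike <- function(p) {
  out <- list()
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is.list(el)) out[[nm]] <- zeroLike(el)
    else if (nm %in% c("W", "b", "gamma", "beta")) out[[nm]] <- el * 0
    else out[[nm]] <- el
  }
  out
}

#' Predict probability maps for a list of samples
#'
#' Applies the full inference path: preprocessing ([preprocessSample()]),
#' eval-mode forward pass, and unpadding back to the original size.
#'
#' @param model a trained model.
#' @param samples list of [FundusSample-class] objects.
#' @param head `"fusion"`, `"decoder1"` or `"decoder2"`.
#' @param claheClip,claheTiles preprocessing parameters.
#' @return list of `H x W` probability matrices.
#' @export
predictSamples <- function(model, samples,
                           head = c("fusion", "decoder1", "decoder2"),
                           claheClip = 2, claheTiles = c(8L, 8L)) {
  head <- match.arg(head)
  if (model$spec$singleBranch) head <- "decoder1"
  lapply(samples, function(s) {
    pp <- preprocessSample(s, claheClip = claheClip,
                           claheTiles = claheTiles,
                           padMultiple = 2L^model$spec$depth)
    out <- netForward(model, pp$input, mode = "eval")
    m <- switch(head, fusion = out$pf, decoder1 = out$p1,
                decoder2 = out$p2)
    cropToOriginal(m, pp$padOffsets, pp$originalSize)
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (spec, parameters, seed)
#' serialized with `saveRDS()`.
#'
#' @param model a model list.
#' @param path file path.
#' @return `loadModel` returns the model; `saveModel` returns `path`
#'   invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
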