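# Minimal CNN engine: layers operate on feature matrices of shape
# (H*W) x C (memory-identical to a column-major H x W x C array), so
# convolutions reduce to one im2col plus one BLAS GEMM. Every layer has an
# explicit forward (returning output + cache) and backward (returning input
# gradient + parameter gradients), composed by hand in model.R.

addBias <- function(m, b) cpp_col_scale(m, rep(1, ncol(m)), b)
bcastCols <- function(m, v) cpp_col_scale(m, v)

heNormalConv <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

# bias is omitted for convolutions feeding a normalization layer (the
# norm's beta subsumes it)
newConv <- function(k, cin, cout, stride = 1L, bias = TRUE) {
  p <- list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
            stride = as.integer(stride),
            W = heNormalConv(k, cin, cout))
  if (bias) p$b <- numeric(cout)
  p
}

convFwd <- function(p, x, H, W) {
  if (p$k == 1 && p$stride == 1) {
    out <- x %*% p$W
    if (!is.null(p$b)) out <- addBias(out, p$b)
    return(list(out = out, H = H, W = W, cache = list(x = x)))
  }
  pad <- (p$k - 1L) %/% 2L
  cols <- conv_im2col(as.numeric(x), H, W, p$cin, p$k, p$stride, pad)
  Ho <- (H + 2L * pad - p$k) %/% p$stride + 1L
  Wo <- (W + 2L * pad - p$k) %/% p$stride + 1L
  out <- cols %*% p$W
  if (!is.null(p$b)) out <- addBias(out, p$b)
  list(out = out, H = Ho, W = Wo, cache = list(cols = cols, H = H, W = W))
}

convBwd <- function(p, cache, dOut) {
  if (p$k == 1 && p$stride == 1) {
    g <- list(dx = tcrossprod(dOut, p$W), dW = crossprod(cache$x, dOut))
    if (!is.null(p$b)) g$db <- colSums(dOut)
    return(g)
  }
  pad <- (p$k - 1L) %/% 2L
  dW <- crossprod(cache$cols, dOut)
  dCols <- tcrossprod(dOut, p$W)
  dx <- conv_col2im(dCols, cache$H, cache$W, p$cin, p$k, p$stride, pad)
  g <- list(dx = matrix(dx, cache$H * cache$W, p$cin), dW = dW)
  if (!is.null(p$b)) g$db <- colSums(dOut)
  g
}

# per-channel normalization over spatial positions (instance norm);
# deterministic at eval time since it uses the instance's own statistics
newNorm <- function(c) list(type = "norm", gamma = rep(1, c), beta = numeric(c))

.NORM_EPS <- 1e-5

normFwd <- function(p, x) {
  r <- cpp_norm_fwd(x, p$gamma, p$beta, .NORM_EPS)
  list(out = r$out, cache = list(xhat = r$xhat, istd = r$istd))
}

normBwd <- function(p, cache, dy) {
  r <- cpp_norm_bwd(dy, cache$xhat, cache$istd, p$gamma)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

reluFwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

reluBwd <- function(cache, dy) dy * cache

rcaFwd <- function(x, params, mode) {
  if (mode != "train" || params$variance == 0)
    return(list(out = x, w = rep(1, ncol(x))))
  w <- sampleChannelWeights(ncol(x), params)
  list(out = bcastCols(x, w), w = w)
}

rcaBwd <- function(w, dy) bcastCols(dy, w)

# nearest-neighbor 2x upsampling via a precomputed row-index map;
# backward is the matching sum-pool. Index maps are memoized per size.
.upsampleCache <- new.env(parent = emptyenv())

upsampleIndex <- function(H, W) {
  key <- paste0(H, "x", W)
  idx <- .upsampleCache[[key]]
  if (is.null(idx)) {
    yo <- rep(seq_len(2L * H), times = 2L * W)
    xo <- rep(seq_len(2L * W), each = 2L * H)
    idx <- ceiling(yo / 2) + (ceiling(xo / 2) - 1L) * H
    .upsampleCache[[key]] <- idx
  }
  idx
}

upsampleFwd <- function(x, H, W) {
  idx <- upsampleIndex(H, W)
  list(out = x[idx, , drop = FALSE], idx = idx)
}

upsampleBwd <- function(idx, dy) {
  dx <- rowsum(dy, group = idx, reorder = TRUE)
  dimnames(dx) <- NULL
  dx
}

# conv -> norm -> relu
newUnit <- function(k, cin, cout, stride = 1L) {
  list(type = "unit", conv = newConv(k, cin, cout, stride, bias = FALSE),
       norm = newNorm(cout))
}

unitFwd <- function(p, x, H, W) {
  cv <- convFwd(p$conv, x, H, W)
  nm <- normFwd(p$norm, cv$out)
  rl <- reluFwd(nm$out)
  list(out = rl$out, H = cv$H, W = cv$W,
       cache = list(cv = cv, nm = nm, rl = rl$cache))
}

unitBwd <- function(p, cache, dy) {
  dy <- reluBwd(cache$rl, dy)
  nb <- normBwd(p$norm, cache$nm$cache, dy)
  cb <- convBwd(p$conv, cache$cv$cache, nb$dx)
  cg <- list(W = cb$dW)
  if (!is.null(cb$db)) cg$b <- cb$db
  list(dx = cb$dx,
       grads = list(conv = cg,
                    norm = list(gamma = nb$dgamma, beta = nb$dbeta)))
}

# residual block: two conv-norm-relu units, RCA on the transformed
# features, then addition of the (possibly 1x1-projected) identity
newRes <- function(cin, cout) {
  p <- list(type = "res",
            u1 = newUnit(3L, cin, cout), u2 = newUnit(3L, cout, cout))
  if (cin != cout) p$proj <- newConv(1L, cin, cout)
  p
}

resFwd <- function(p, x, H, W, rca, mode) {
  u1 <- unitFwd(p$u1, x, H, W)
  u2 <- unitFwd(p$u2, u1$out, H, W)
  rc <- rcaFwd(u2$out, rca, mode)
  if (!is.null(p$proj)) {
    pj <- convFwd(p$proj, x, H, W)
    out <- rc$out + pj$out
  } else {
    pj <- NULL
    out <- rc$out + x
  }
  list(out = out, H = H, W = W,
       cache = list(u1 = u1, u2 = u2, w = rc$w, pj = pj))
}

resBwd <- function(p, cache, dy) {
  dtrans <- rcaBwd(cache$w, dy)
  b2 <- unitBwd(p$u2, cache$u2$cache, dtrans)
  b1 <- unitBwd(p$u1, cache$u1$cache, b2$dx)
  grads <- list(u1 = b1$grads, u2 = b2$grads)
  if (!is.null(p$proj)) {
    pb <- convBwd(p$proj, cache$pj$cache, dy)
    dx <- b1$dx + pb$dx
    grads$proj <- list(W = pb$dW, b = pb$db)
  } else {
    dx <- b1$dx + dy
  }
  list(dx = dx, grads = grads)
}

sigmoidStable <- function(z) 1 / (1 + exp(-pmin(pmax(z, -40), 40)))
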