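# shared fixtures and independent oracles, all built in code

# small deterministic fundus sample
smallSample <- function(seed = 5, size = 64) {
  cfg <- synthConfig(height = size, width = size, seed = seed)
  renderFundus(generateVesselTree(cfg), cfg)
}

# convolution-based morphology oracle (independent of the package's
# shift-and-combine implementation): erosion demands a full footprint,
# dilation any overlap; zero boundary
oracleErode <- function(mask, se) {
  f <- EBImage::filter2(mask, se[nrow(se):1, ncol(se):1], boundary = 0)
  (f >= sum(se) - 0.5) * 1
}

oracleDilate <- function(mask, se) {
  f <- EBImage::filter2(mask, se[nrow(se):1, ncol(se):1], boundary = 0)
  (f >= 0.5) * 1
}

# literal double-loop set-definition oracle (slow; for tiny masks)
oracleErodeLoop <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask); r <- (nrow(se) - 1) / 2
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    ok <- TRUE
    for (dy in -r:r) for (dx in -r:r) {
      if (se[dy + r + 1, dx + r + 1] == 0) next
      yy <- y + dy; xx <- x + dx
      v <- if (yy < 1 || yy > H || xx < 1 || xx > W) 0 else mask[yy, xx]
      if (v == 0) ok <- FALSE
    }
    out[y, x] <- as.numeric(ok)
  }
  out
}

oracleDilateLoop <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask); r <- (nrow(se) - 1) / 2
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    hit <- FALSE
    for (dy in -r:r) for (dx in -r:r) {
      if (se[dy + r + 1, dx + r + 1] == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W && mask[yy, xx] == 1)
        hit <- TRUE
    }
    out[y, x] <- as.numeric(hit)
  }
  out
}

randomMask <- function(n = 32, p = 0.4) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# number of 8-connected foreground components
components8 <- function(mask) {
  idx <- which(mask == 1)
  if (length(idx) == 0) return(0)
  H <- nrow(mask)
  id <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  id[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)][idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    a <- id[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
    b <- id[2:(nrow(mask) + 1) + off[1], 2:(ncol(mask) + 1) + off[2]]
    keep <- a > 0 & b > 0
    edges <- c(edges, rbind(a[keep], b[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

# finite-difference gradient of a scalar-valued function of one leaf
fdGrad <- function(lossFn, value, i, h = 1e-6) {
  vp <- value; vp[i] <- value[i] + h
  vm <- value; vm[i] <- value[i] - h
  (lossFn(vp) - lossFn(vm)) / (2 * h)
}
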