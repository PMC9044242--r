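# correctness of the hand-rolled CNN engine: layer-level gradients are
# checked by central finite differences, the full model by an exhaustive
# leaf sweep on a tiny configuration (random inputs keep pre-activations
# away from ReLU kinks, where subgradients make FD comparison undefined)

test_that("layer backward passes match finite differences", {
  set.seed(81)
  H <- 6; W <- 6; C <- 3
  X <- matrix(rnorm(H * W * C), H * W, C)
  checkLayer <- function(fwd, bwd, X, R) {
    dX <- bwd(X, R)
    for (i in sample(length(X), 3)) {
      fd <- fdGrad(function(x) sum(fwd(x) * R), X, i)
      expect_equal(dX[i], fd, tolerance = 1e-5)
    }
  }
  ng <- vesselseg:::newNorm(C)
  R <- matrix(rnorm(H * W * C), H * W, C)
  checkLayer(function(x) vesselseg:::normFwd(ng, x)$out,
             function(x, r) {
               f <- vesselseg:::normFwd(ng, x)
               vesselseg:::normBwd(ng, f$cache, r)$dx
             }, X, R)
  cv <- vesselseg:::withSeed(1, vesselseg:::newConv(3, C, 4))
  R4 <- matrix(rnorm(H * W * 4), H * W, 4)
  checkLayer(function(x) vesselseg:::convFwd(cv, x, H, W)$out,
             function(x, r) {
               f <- vesselseg:::convFwd(cv, x, H, W)
               vesselseg:::convBwd(cv, f$cache, r)$dx
             }, X, R4)
  cv2 <- vesselseg:::withSeed(2, vesselseg:::newConv(3, C, 4, stride = 2))
  R42 <- matrix(rnorm(H * W), H * W / 4, 4)
  checkLayer(function(x) vesselseg:::convFwd(cv2, x, H, W)$out,
             function(x, r) {
               f <- vesselseg:::convFwd(cv2, x, H, W)
               vesselseg:::convBwd(cv2, f$cache, r)$dx
             }, X, R42)
  Rup <- matrix(rnorm(4 * H * W * C), 4 * H * W, C)
  checkLayer(function(x) vesselseg:::upsampleFwd(x, H, W)$out,
             function(x, r) {
               f <- vesselseg:::upsampleFwd(x, H, W)
               vesselseg:::upsampleBwd(f$idx, r)
             }, X, Rup)
  rs <- vesselseg:::withSeed(3, vesselseg:::newRes(C, C))
  rp <- rcaParams(variance = 0)
  checkLayer(function(x) vesselseg:::resFwd(rs, x, H, W, rp, "eval")$out,
             function(x, r) {
               f <- vesselseg:::resFwd(rs, x, H, W, rp, "eval")
               vesselseg:::resBwd(rs, f$cache, r)$dx
             }, X, R)
})

test_that("whole-model gradients match finite differences on every leaf", {
  set.seed(82)
  H <- 16; W <- 16
  item <- list(input = matrix(runif(H * W), H, W),
               label = matrix(rbinom(H * W, 1, 0.2), H, W),
               fov = matrix(1, H, W),
               weights = matrix(1 + 2 * rbinom(H * W, 1, 0.3), H, W))
  tc <- stagedTrainConfig()
  spec <- modelSpec(depth = 1, baseChannels = 2,
                    rca = rcaParams(variance = 0))
  m <- buildDbfuNet(spec, seed = 2)
  heads <- c("d1", "d2", "fusion")
  kinds <- c("bce", "weighted_bce", "dice")
  lossAt <- function(model)
    vesselseg:::itemLoss(model, item, heads, kinds, tc, "eval")$loss
  r <- vesselseg:::itemLoss(m, item, heads, kinds, tc, "eval", TRUE)
  walk <- function(pth) {
    p <- m$params; g <- r$grads
    for (k in pth) { p <- p[[k]]; g <- g[[k]] }
    last <- pth[length(pth)]
    if (last %in% c("W", "b", "gamma", "beta")) {
      for (i in sample(length(p), min(2, length(p)))) {
        m2 <- m
        leaf <- paste0("m2$params[[\"",
                       paste(pth, collapse = "\"]][[\""), "\"]]")
        v0 <- p[i]
        eval(parse(text = paste0(leaf, "[i] <- v0 + 1e-6")))
        lp <- lossAt(m2)
        eval(parse(text = paste0(leaf, "[i] <- v0 - 1e-6")))
        lm <- lossAt(m2)
        fd <- (lp - lm) / 2e-6
        expect_lt(abs(g[i] - fd), 1e-6 + 1e-4 * abs(fd),
                  label = paste("grad mismatch at",
                                paste(c(pth, i), collapse = "/")))
      }
    } else if (is.list(p)) {
      for (nm in names(p)) walk(c(pth, nm))
    }
  }
  for (grp in names(m$params)) walk(grp)
})

test_that("model construction is seeded-deterministic and geometry-checked", {
  spec <- modelSpec(depth = 5, baseChannels = 2)
  m1 <- buildDbfuNet(spec, seed = 7)
  m2 <- buildDbfuNet(spec, seed = 7)
  expect_identical(m1$params, m2$params)
  x64 <- matrix(runif(64 * 64), 64, 64)
  expect_silent(netForward(m1, x64))
  expect_error(netForward(m1, matrix(0.5, 65, 65)), "divisible")
  expect_error(modelSpec(depth = 0), "depth")
})

test_that("forward outputs are probabilities at input resolution, eval deterministic", {
  m <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4), seed = 3)
  x <- matrix(runif(32 * 32), 32, 32)
  o1 <- netForward(m, x, mode = "eval")
  o2 <- netForward(m, x, mode = "eval")
  for (p in o1[c("p1", "p2", "pf")]) {
    expect_equal(dim(p), c(32, 32))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_identical(o1, o2)
})

test_that("train mode is stochastic through RCA, and variance 0 removes it", {
  x <- matrix(runif(32 * 32), 32, 32)
  m <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4), seed = 3)
  set.seed(83)
  t1 <- netForward(m, x, mode = "train")
  t2 <- netForward(m, x, mode = "train")
  expect_gt(max(abs(t1$pf - t2$pf)), 0)
  m0 <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4,
                               rca = rcaParams(variance = 0)), seed = 3)
  e <- netForward(m0, x, mode = "eval")
  t <- netForward(m0, x, mode = "train")
  expect_identical(e, t)
})

test_that("the double-branch model has more parameters than the single branch", {
  spec <- modelSpec(depth = 3, baseChannels = 4)
  dual <- buildDbfuNet(spec, seed = 1)
  single <- buildDbfuNet(modelSpec(depth = 3, baseChannels = 4,
                                   singleBranch = TRUE), seed = 1)
  expect_gt(parameterCount(dual), parameterCount(single))
})

test_that("a reduced model runs a forward pass quickly on CPU", {
  m <- buildDbfuNet(modelSpec(depth = 3, baseChannels = 8), seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  invisible(netForward(m, x))  # warm up
  t0 <- Sys.time()
  invisible(netForward(m, x))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})

test_that("checkpoints round-trip through save/load", {
  m <- buildDbfuNet(modelSpec(depth = 1, baseChannels = 2), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$spec, m2$spec)
})
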