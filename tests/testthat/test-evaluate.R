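test_that("gray map rescaling follows round(p * 255) and is monotone", {
  expect_equal(toGrayMap(matrix(c(0, 1), 1, 2)), matrix(c(0, 255), 1, 2))
  expect_equal(toGrayMap(matrix(0.5)), matrix(128))
  set.seed(61)
  p <- sort(runif(100))
  g <- toGrayMap(matrix(p, 1, 100))
  expect_true(all(diff(as.numeric(g)) >= 0))
  expect_error(toGrayMap(matrix(1.2)), "0,1")
})

test_that("binarization thresholds with >= and matches the comparison oracle", {
  g <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_equal(binarize(g, 0), matrix(1, 2, 2))
  expect_equal(binarize(g, 100), (g >= 100) * 1)
  expect_equal(sum(binarize(matrix(0:254, 5, 51), 255)), 0)
  set.seed(62)
  g <- matrix(sample(0:255, 400, TRUE), 20, 20)
  t <- sample(0:255, 1)
  expect_equal(binarize(g, t), (g >= t) * 1)
})

test_that("confusion counts pool over images and ignore non-FOV pixels", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  f <- matrix(1, 2, 2)
  cc <- confusionCounts(y, y, f)
  expect_equal(cc@fp + cc@fn, 0)
  expect_equal(cc@tp + cc@tn + cc@fp + cc@fn, sum(f))
  # flipping predictions outside the FOV changes nothing
  f2 <- matrix(c(1, 1, 0, 0), 2, 2)
  p <- matrix(c(1, 0, 0, 1), 2, 2)
  c1 <- confusionCounts(p, y, f2)
  pFlip <- p; pFlip[f2 == 0] <- 1 - pFlip[f2 == 0]
  c2 <- confusionCounts(pFlip, y, f2)
  expect_equal(c(c1@tp, c1@tn, c1@fp, c1@fn), c(c2@tp, c2@tn, c2@fp, c2@fn))
  # pooling over a list equals summing individual counts
  cc2 <- confusionCounts(list(p, y), list(y, y), list(f2, f))
  expect_equal(cc2@tp, c1@tp + cc@tp)
})

test_that("all-negative prediction at 1:9 imbalance gives Acc 0.90, Se 0", {
  m <- computeMetrics(confusionFromCounts(tp = 0, tn = 900, fp = 0,
                                          fn = 100))
  expect_equal(m@acc, 0.9)
  expect_equal(m@se, 0)
})

test_that("perfect prediction maximizes every metric", {
  m <- computeMetrics(confusionFromCounts(tp = 50, tn = 450, fp = 0,
                                          fn = 0))
  expect_equal(c(m@acc, m@se, m@sp, m@f1, m@gmean, m@mcc), rep(1, 6))
})

test_that("G-mean recomputed from published Se/Sp matches the printed column", {
  b <- publishedBenchmarks()
  for (i in seq_len(nrow(b))) {
    cc <- confusionFromCounts(tp = b$se[i] * 1e6,
                              fn = (1 - b$se[i]) * 1e6,
                              tn = b$sp[i] * 9e6,
                              fp = (1 - b$sp[i]) * 9e6)
    m <- computeMetrics(cc)
    expect_equal(round(m@gmean, 4), b$g[i])
  }
})

test_that("MCC variants: standard is signed, as-printed is not Matthews", {
  cc <- confusionFromCounts(tp = 10, tn = 10, fp = 90, fn = 90)
  std <- computeMetrics(cc, mccVariant = "standard")@mcc
  lit <- computeMetrics(cc, mccVariant = "as-printed")@mcc
  expect_lt(std, 0)   # anti-correlated prediction
  expect_gt(lit, 0)   # the printed variant cannot be negative
  # equality of both variants on a symmetric perfect case
  p <- confusionFromCounts(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(computeMetrics(p, "standard")@mcc, 1)
})

test_that("metric identities hold on random confusion counts", {
  set.seed(63)
  for (i in 1:20) {
    v <- rmultinom(1, 1000, runif(4, 0.05, 1))
    m <- computeMetrics(confusionFromCounts(v[1], v[2], v[3], v[4]))
    expect_equal(m@gmean, sqrt(m@se * m@sp), tolerance = 1e-12)
    prev <- (v[1] + v[4]) / 1000
    expect_equal(m@acc, prev * m@se + (1 - prev) * m@sp, tolerance = 1e-12)
    expect_true(m@mcc >= -1 && m@mcc <= 1)
  }
})

test_that("AUC: separation gives 1, constancy 0.5, toy case matches pair counting", {
  f <- matrix(1, 2, 5)
  y <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2, 5)
  sep <- matrix(ifelse(y == 1, 0.9, 0.1), 2, 5)
  expect_equal(computeAUC(sep, y, f), 1)
  expect_equal(computeAUC(matrix(0.5, 2, 5), y, f), 0.5)
  set.seed(64)
  s <- matrix(runif(10), 2, 5)
  pairs <- expand.grid(p = s[y == 1], n = s[y == 0])
  oracle <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
  expect_equal(computeAUC(s, y, f), oracle, tolerance = 1e-12)
  expect_error(computeAUC(s, matrix(1, 2, 5), f), "single class")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(65)
  y <- matrix(rbinom(200, 1, 0.3), 10, 20)
  s <- matrix(runif(200), 10, 20)
  f <- matrix(1, 10, 20)
  ours <- computeAUC(s, y, f)
  ref <- as.numeric(pROC::auc(as.numeric(y), as.numeric(s),
                              direction = "<", quiet = TRUE))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(computeAUC(s^3, y, f), ours, tolerance = 1e-12)
  expect_equal(computeAUC(plogis(5 * s - 2), y, f), ours, tolerance = 1e-12)
})

test_that("threshold selection maximizes pooled F1 with low tie-break", {
  g <- matrix(50, 8, 8); y <- matrix(0, 8, 8); f <- matrix(1, 8, 8)
  g[3:5, 3:5] <- 200; y[3:5, 3:5] <- 1
  expect_equal(selectThreshold(g, y, f), 51)
  set.seed(66)
  for (i in 1:10) {
    g <- matrix(sample(0:255, 256, TRUE), 16, 16)
    y <- randomMask(16, 0.2)
    f <- randomMask(16, 0.9)
    got <- selectThreshold(g, y, f)
    f1At <- function(t) {
      cc <- confusionCounts(binarize(g, t), y, f)
      computeMetrics(cc)@f1
    }
    scan <- vapply(0:255, f1At, numeric(1))
    expect_equal(got, which.max(scan) - 1L)
    expect_true(got >= 0 && got <= 255)
  }
})
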