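test_that("structuring elements are symmetric and correctly shaped", {
  for (sh in c("square", "cross", "disk")) {
    se <- structuringElement(sh, 2)
    expect_equal(dim(se), c(5, 5))
    expect_equal(unclass(se), se[5:1, 5:1], ignore_attr = TRUE)
    expect_equal(se[3, 3], 1)
  }
  expect_equal(sum(structuringElement("cross", 1)), 5)
  expect_error(structuringElement("square", 0), "radius")
})

test_that("erosion and dilation match their set definitions", {
  se <- structuringElement("square", 1)
  m <- matrix(1, 5, 5)
  e <- binaryErode(m, se)
  expect_equal(sum(e), 9)
  expect_equal(e[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(binaryErode(matrix(0, 4, 4), se), matrix(0, 4, 4))
  d0 <- matrix(0, 5, 5); d0[3, 3] <- 1
  d <- binaryDilate(d0, se)
  expect_equal(sum(d), 9)
  expect_equal(d[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(binaryDilate(matrix(0, 4, 4), se), matrix(0, 4, 4))
  expect_error(binaryErode(matrix(0.5, 3, 3), se), "0, 1")
})

test_that("morphology agrees with a convolution oracle on random masks", {
  set.seed(71)
  for (sh in c("square", "cross", "disk")) {
    se <- structuringElement(sh, 1)
    for (i in 1:40) {
      m <- randomMask(32)
      expect_equal(binaryErode(m, se), oracleErode(m, se))
      expect_equal(binaryDilate(m, se), oracleDilate(m, se))
    }
  }
})

test_that("erosion/dilation duality holds on complements away from borders", {
  # with the outside-is-background convention the identity
  # dilate(A) = !erode(!A) can only hold where the border assumption is
  # not visible, i.e. at least one SE radius inside the image
  set.seed(72)
  se <- structuringElement("square", 1)
  inner <- 2:23
  for (i in 1:25) {
    m <- randomMask(24)
    expect_equal(binaryDilate(m, se)[inner, inner],
                 (1 - binaryErode(1 - m, se + 0))[inner, inner])
  }
})

test_that("hard mask of an empty label is empty", {
  expect_equal(extractHardMask(matrix(0, 16, 16)), matrix(0, 16, 16))
})

test_that("a 1-px line has an empty eroded core, so its hard mask is its dilation", {
  L <- matrix(0, 9, 9); L[5, 2:8] <- 1
  se <- structuringElement("square", 1)
  expect_equal(binaryErode(L, se), matrix(0, 9, 9))
  expect_equal(extractHardMask(L, se, se), binaryDilate(L, se))
})

test_that("a thick square keeps only its edge band in the hard mask", {
  L <- matrix(0, 11, 11); L[4:8, 4:8] <- 1
  se <- structuringElement("square", 1)
  mask <- extractHardMask(L, se, se)
  want <- matrix(0, 11, 11); want[3:9, 3:9] <- 1; want[5:7, 5:7] <- 0
  expect_equal(mask, want)
})

test_that("hard mask = (dilate(label - erode(label))) - erode(label) on random labels", {
  set.seed(73)
  se <- structuringElement("square", 1)
  for (i in 1:30) {
    L <- randomMask(24, p = 0.3)
    B <- oracleErode(L, se)
    D <- oracleDilate(L * (1 - B), se)
    expect_equal(extractHardMask(L, se, se), D * (1 - B))
  }
})

test_that("hard mask never overlaps the eroded core and covers all thin positives", {
  set.seed(74)
  se <- structuringElement("square", 1)
  for (i in 1:30) {
    L <- randomMask(24, p = 0.35)
    B <- binaryErode(L, se)
    mask <- extractHardMask(L, se, se)
    expect_equal(sum(mask * B), 0)
    thin <- L * (1 - B)
    expect_true(all(mask[thin == 1] == 1))
  }
})

test_that("hard weight map follows mask * weight + 1", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(hardWeightMap(m, 2), m * 2 + 1)
  expect_equal(hardWeightMap(m, 0), matrix(1, 2, 2))
  expect_equal(min(hardWeightMap(randomMask(8), 5)), 1)
  expect_error(hardWeightMap(m, -1), "non-negative")
})

test_that("probability band mask marks the undecided range", {
  pm <- matrix(c(0.1, 0.5, 0.9), 1, 3)
  expect_equal(probabilityBandMask(pm, 0.4, 0.6),
               matrix(c(0, 1, 0), 1, 3))
  expect_equal(probabilityBandMask(pm, 0, 1), matrix(1, 1, 3))
  set.seed(75)
  pm <- matrix(runif(100), 10, 10)
  expect_equal(probabilityBandMask(pm, 0.3, 0.7),
               (pm >= 0.3 & pm <= 0.7) * 1)
  expect_error(probabilityBandMask(pm, 0.7, 0.3), "band")
})
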