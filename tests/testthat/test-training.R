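test_that("learning-rate schedule decays by 1/3 at each third of a segment", {
  p <- phaseConfig()
  expect_equal(lrAt(p, 0), 7e-4)
  expect_equal(lrAt(p, 0.34), 7e-4 / 3)
  expect_equal(lrAt(p, 0.67), 7e-4 / 9)
  expect_equal(lrAt(p, 0.99), 7e-4 / 9)
  expect_error(lrAt(p, 1), "lie in")
  expect_error(lrAt(p, -0.1), "lie in")
})

test_that("train/validation split is disjoint, covering, reproducible", {
  samples <- as.list(letters[1:20])
  sp <- splitTrainValidation(samples, 0.10, seed = 5)
  expect_length(sp$train, 18)
  expect_length(sp$validation, 2)
  expect_setequal(c(unlist(sp$train), unlist(sp$validation)), letters[1:20])
  sp2 <- splitTrainValidation(samples, 0.10, seed = 5)
  expect_identical(sp, sp2)
  expect_error(splitTrainValidation(samples, 0.01, seed = 1), "empty")
})

test_that("k-fold splits have balanced folds covering every index once", {
  f5 <- kfoldSplit(20, 5, seed = 2)
  expect_length(f5, 5)
  expect_true(all(vapply(f5, function(f) length(f$test), integer(1)) == 4))
  expect_setequal(unlist(lapply(f5, `[[`, "test")), 1:20)
  f4 <- kfoldSplit(14, 4, seed = 2)
  sizes <- sort(vapply(f4, function(f) length(f$test), integer(1)))
  expect_equal(sizes, c(3, 3, 4, 4))
  for (f in f4) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:14)
  }
  expect_error(kfoldSplit(5, 6, seed = 1), "k must be")
})

test_that("frozen groups are bit-identical across a training segment", {
  set.seed(91)
  samples <- generateFundusDataset(3, synthConfig(height = 64, width = 64,
                                                  seed = 30))
  tc <- stagedTrainConfig(seed = 4)
  m <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4), seed = 6)
  valItems <- lapply(samples[3], vesselseg:::prepareTrainItem, config = tc,
                     model = m, augmentSeed = NULL)
  hist <- list(steps = list(), epochs = list())
  phase2 <- phaseConfig("decoder2", "weighted_bce", epochs = 1)
  r <- vesselseg:::withSeed(1,
    vesselseg:::trainSegment(m, samples[1:2], valItems, phase2, 2L, "main",
                             tc, hist, stepSeed = 7))
  expect_identical(r$model$params$encoder, m$params$encoder)
  expect_identical(r$model$params$decoder1, m$params$decoder1)
  expect_identical(r$model$params$fusion, m$params$fusion)
  expect_false(identical(r$model$params$decoder2, m$params$decoder2))
})

test_that("SGD with momentum updates only the selected groups", {
  m <- buildDbfuNet(modelSpec(depth = 1, baseChannels = 2), seed = 8)
  g <- vesselseg:::zeroLike(m$params)
  g$decoder1$head$W[] <- 1
  upd <- vesselseg:::sgdUpdate(m$params, g, list(), lr = 0.1,
                               groups = "decoder1")
  expect_equal(upd$params$decoder1$head$W,
               m$params$decoder1$head$W - 0.1, ignore_attr = TRUE)
  expect_identical(upd$params$encoder, m$params$encoder)
  # momentum accumulates over a second identical step
  upd2 <- vesselseg:::sgdUpdate(upd$params, g, upd$vel, lr = 0.1,
                                groups = "decoder1")
  expect_equal(upd2$params$decoder1$head$W,
               m$params$decoder1$head$W - 0.1 - 0.19, ignore_attr = TRUE)
})

test_that("a 1-epoch-per-segment staged run executes all five segments in order", {
  set.seed(92)
  samples <- generateFundusDataset(4, synthConfig(height = 64, width = 64,
                                                  seed = 40))
  tc <- stagedTrainConfig(
    phase1 = phaseConfig(c("encoder", "decoder1"), "bce", epochs = 1),
    phase2 = phaseConfig("decoder2", "weighted_bce", epochs = 1,
                         fineTuneLr = 5e-5, fineTuneEpochs = 1),
    phase3 = phaseConfig("fusion", "bce", epochs = 1,
                         fineTuneLr = 5e-5, fineTuneEpochs = 1),
    validationFraction = 0.25, seed = 9)
  m <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4), seed = 10)
  r <- runStagedTraining(m, samples, tc)
  ep <- r$history$epochs
  expect_equal(paste(ep$phase, ep$segment),
               c("1 main", "2 main", "2 finetune", "3 main", "3 finetune"))
  expect_true(all(is.finite(ep$valLoss)))
  expect_true(all(is.finite(r$history$steps$loss)))
  expect_true(all(r$history$steps$loss >= 0))
})

test_that("staged training histories are reproducible under a fixed seed", {
  samples <- generateFundusDataset(3, synthConfig(height = 64, width = 64,
                                                  seed = 50))
  tc <- stagedTrainConfig(
    phase1 = phaseConfig(c("encoder", "decoder1"), "bce", epochs = 1),
    phase2 = phaseConfig("decoder2", "weighted_bce", epochs = 1,
                         fineTuneLr = NULL, fineTuneEpochs = 0),
    phase3 = phaseConfig("fusion", "bce", epochs = 1,
                         fineTuneLr = NULL, fineTuneEpochs = 0),
    validationFraction = 0.34, seed = 12)
  m <- buildDbfuNet(modelSpec(depth = 2, baseChannels = 4), seed = 13)
  r1 <- runStagedTraining(m, samples, tc)
  r2 <- runStagedTraining(m, samples, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})
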