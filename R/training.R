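#' Learning rate within a training segment
#'
#' The base learning rate is multiplied by 1/3 at each third of the
#' segment: `lr = baseLr * (1/3)^floor(3 * progress)`, giving three decay
#' steps per segment. (Read literally as a decay every third of a single
#' epoch, the rate would shrink by (1/3)^36 over a 12-epoch segment and
#' vanish numerically; the per-segment reading keeps it in a usable
#' range.)
#'
#' @param phase a [phaseConfig()] (its `baseLr` is used).
#' @param epochProgress fraction of the segment elapsed, in `[0, 1)`.
#' @return the learning rate.
#' @examples
#' lrAt(phaseConfig(), 0)     # 7e-4
#' lrAt(phaseConfig(), 0.34)  # 7e-4 / 3
#' @export
lrAt <- function(phase, epochProgress) {
  if (epochProgress < 0 || epochProgress >= 1)
    stop("epochProgress must lie in [0, 1)")
  phase$baseLr * (1 / 3)^floor(3 * epochProgress)
}

#' Split samples into training and validation sets
#'
#' @param samples list of samples.
#' @param fraction validation fraction in (0, 0.5) (default 0.10).
#' @param seed integer seed; the split is reproducible.
#' @return list with `train` and `validation` (disjoint, covering).
#' @export
splitTrainValidation <- function(samples, fraction = 0.10, seed = 1L) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  nVal <- round(n * fraction)
  if (nVal < 1 || nVal >= n)
    stop("fraction yields an empty partition")
  idx <- withSeed(seed, base::sample.int(n))
  list(train = samples[sort(idx[-seq_len(nVal)])],
       validation = samples[sort(idx[seq_len(nVal)])])
}

#' k-fold cross-validation split
#'
#' Shuffles indices under the seed and deals them into `k` disjoint test
#' folds whose sizes differ by at most one (the five-fold / four-fold
#' protocol used for STARE and CHASE, which ship no official test split).
#'
#' @param nSamples total number of samples.
#' @param k number of folds, `2 <= k <= nSamples`.
#' @param seed integer seed.
#' @return list of `k` lists with integer `train` and `test` indices.
#' @export
kfoldSplit <- function(nSamples, k, seed = 1L) {
  if (k < 2 || k > nSamples) stop("k must be in [2, nSamples]")
  idx <- withSeed(seed, base::sample.int(nSamples))
  sizes <- rep(nSamples %/% k, k)
  if (nSamples %% k > 0) sizes[seq_len(nSamples %% k)] <- sizes[1] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(idx[starts[i]:ends[i]])
    list(train = setdiff(seq_len(nSamples), test), test = test)
  })
}

#' Configuration of one training phase
#'
#' @param trainableGroups character subset of
#'   `c("encoder", "decoder1", "decoder2", "fusion")` updated during the
#'   phase's main segment; all other groups are frozen bit-exact.
#' @param lossKind `"bce"`, `"weighted_bce"`, `"focal"` or `"dice"`.
#' @param baseLr initial learning rate of the main segment (default 7e-4,
#'   decayed by [lrAt()]).
#' @param epochs main-segment epochs (>= 1).
#' @param fineTuneLr constant learning rate of the fine-tune segment in
#'   which all parameters are unfrozen, or `NULL` for no fine-tuning.
#' @param fineTuneEpochs fine-tune epochs.
#' @param batchSize minibatch size (default 2).
#' @param optimizer `"sgd"` (momentum 0.9).
#' @return a `phaseConfig` list.
#' @export
phaseConfig <- function(trainableGroups = c("encoder", "decoder1"),
                        lossKind = "bce", baseLr = 7e-4, epochs = 12L,
                        fineTuneLr = NULL, fineTuneEpochs = 0L,
                        batchSize = 2L, optimizer = "sgd") {
  if (epochs < 1) stop("epochs must be >= 1")
  if (baseLr <= 0) stop("baseLr must be positive")
  lossKind <- match.arg(lossKind, c("bce", "weighted_bce", "focal", "dice"))
  optimizer <- match.arg(optimizer, "sgd")
  structure(list(trainableGroups = trainableGroups, lossKind = lossKind,
                 baseLr = baseLr, epochs = as.integer(epochs),
                 fineTuneLr = fineTuneLr,
                 fineTuneEpochs = as.integer(fineTuneEpochs),
                 batchSize = as.integer(batchSize), optimizer = optimizer),
            class = "phaseConfig")
}

#' Configuration of the full staged training procedure
#'
#' The default reproduces the published schedule: phase 1 trains encoder +
#' decoder 1 with plain cross-entropy for 12 epochs; phase 2 freezes the
#' encoder and trains decoder 2 with the hard-example-weighted loss for 12
#' epochs, then fine-tunes all parameters for 8 epochs at 5e-5; phase 3
#' freezes everything but the fusion layer for 6 epochs, then fine-tunes
#' all parameters for 4 epochs at 5e-5. Fresh parameter groups (decoder 2,
#' fusion) are he-normal re-initialized at their phase start. During
#' fine-tune segments the losses of all heads trained so far are summed.
#'
#' @param phase1,phase2,phase3 [phaseConfig()] objects.
#' @param validationFraction fraction held out for validation (default
#'   0.10).
#' @param weightHyper hard-example weight hyperparameter (see
#'   [hardWeightMap()]).
#' @param augment list of augmentation settings:
#'   `enabled`, `rotations`, `mirror`, `translateMax`,
#'   `elastic` (list `alpha`, `sigma`, `prob`).
#' @param lossInFov if `TRUE`, restrict the training loss to FOV pixels;
#'   by default the loss runs over all padded pixels (padded regions carry
#'   zero label and weight 1).
#' @param selectBest if `TRUE` (default), each segment ends with the
#'   parameters of its best-validation-loss epoch.
#' @param seed master seed for data order, augmentation and RCA.
#' @return a `stagedTrainConfig` list.
#' @export
stagedTrainConfig <- function(
    phase1 = phaseConfig(c("encoder", "decoder1"), "bce", epochs = 12L),
    phase2 = phaseConfig("decoder2", "weighted_bce", epochs = 12L,
                         fineTuneLr = 5e-5, fineTuneEpochs = 8L),
    phase3 = phaseConfig("fusion", "bce", epochs = 6L,
                         fineTuneLr = 5e-5, fineTuneEpochs = 4L),
    validationFraction = 0.10, weightHyper = 2,
    augment = list(enabled = TRUE, rotations = c(0, 90, 180, 270),
                   mirror = TRUE, translateMax = 8L,
                   elastic = list(alpha = 8, sigma = 8, prob = 0.5)),
    lossInFov = FALSE, selectBest = TRUE, seed = 1L) {
  if (!(validationFraction > 0 && validationFraction < 0.5))
    stop("validationFraction must lie in (0, 0.5)")
  structure(list(phase1 = phase1, phase2 = phase2, phase3 = phase3,
                 validationFraction = validationFraction,
                 weightHyper = weightHyper, augment = augment,
                 lossInFov = lossInFov, selectBest = isTRUE(selectBest),
                 seed = as.integer(seed)),
            class = "stagedTrainConfig")
}

# --- loss value + logit gradient ------------------------------------------

lossAndGrad <- function(kind, p, y, weights = NULL, gamma = 2,
                        eps = 1e-5, mask = NULL) {
  n <- length(p)
  pc <- clip01(p, .EPS_CLIP)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask == 1
  nEff <- sum(keep)
  if (kind == "bce" || kind == "weighted_bce") {
    w <- if (is.null(weights)) rep(1, n) else weights
    ce <- -(y * log(pc) + (1 - y) * log(1 - pc)) * w
    dz <- (p - y) * w / nEff
    value <- sum(ce[keep]) / nEff
  } else if (kind == "focal") {
    pt <- ifelse(y == 1, pc, 1 - pc)
    fl <- -(1 - pt)^gamma * log(pt)
    dP <- ifelse(y == 1,
                 gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc,
                 -gamma * pc^(gamma - 1) * log(1 - pc) + pc^gamma / (1 - pc))
    dz <- dP * pc * (1 - pc) / nEff
    value <- sum(fl[keep]) / nEff
  } else if (kind == "dice") {
    yk <- y[keep]; pk <- p[keep]
    I <- sum(yk * pk); U <- sum(yk) + sum(pk)
    value <- 1 - (2 * I + eps) / (U + eps)
    dP <- -(2 * y * (U + eps) - (2 * I + eps)) / (U + eps)^2
    dz <- dP * p * (1 - p)
  } else stop("unknown loss kind: ", kind)
  if (!is.null(mask)) dz[!keep] <- 0
  list(value = value, dz = dz)
}

# --- SGD with momentum over nested parameter lists ------------------------

isLeafName <- function(nm) nm %in% c("W", "b", "gamma", "beta")

sgdUpdate <- function(params, grads, vel, lr, momentum = 0.9,
                      groups = names(params)) {
  step <- function(p, g, v) {
    for (nm in names(p)) {
      if (isLeafName(nm)) {
        if (is.null(v[[nm]])) v[[nm]] <- p[[nm]] * 0
        v[[nm]] <- momentum * v[[nm]] - lr * g[[nm]]
        p[[nm]] <- p[[nm]] + v[[nm]]
      } else if (is.list(p[[nm]])) {
        r <- step(p[[nm]], g[[nm]], if (is.null(v[[nm]])) list() else v[[nm]])
        p[[nm]] <- r$p; v[[nm]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  for (grp in groups) {
    if (is.null(params[[grp]])) next
    r <- step(params[[grp]], grads[[grp]],
              if (is.null(vel[[grp]])) list() else vel[[grp]])
    params[[grp]] <- r$p; vel[[grp]] <- r$v
  }
  list(params = params, vel = vel)
}

addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    if (is.list(b[[nm]])) a[[nm]] <- addGrads(a[[nm]], b[[nm]])
    else if (isLeafName(nm)) a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}

scaleGrads <- function(g, s) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) g[[nm]] <- scaleGrads(g[[nm]], s)
    else if (isLeafName(nm)) g[[nm]] <- g[[nm]] * s
  }
  g
}

# --- data plumbing ---------------------------------------------------------

# augment (training only) and preprocess one sample; returns network input,
# padded label/fov and the per-pixel weight map for the weighted loss
prepareTrainItem <- function(sample, config, model, augmentSeed = NULL) {
  if (!is.null(augmentSeed) && isTRUE(config$augment$enabled)) {
    a <- config$augment
    sample <- augmentGeometric(sample, seed = augmentSeed,
                               rotations = a$rotations, mirror = a$mirror,
                               translateMax = a$translateMax)
    el <- a$elastic
    if (!is.null(el) && withSeed(augmentSeed + 1, runif(1)) < el$prob)
      sample <- elasticDeform(sample, alpha = el$alpha, sigma = el$sigma,
                              seed = augmentSeed + 2)
  }
  pp <- preprocessSample(sample, padMultiple = 2L^model$spec$depth)
  # hard mask from the (augmented) label, so mask and label stay aligned
  hard <- extractHardMask(pp$label)
  weights <- hardWeightMap(hard, config$weightHyper)
  list(input = pp$input, label = pp$label, fov = pp$fov, weights = weights)
}

headLossSpec <- function(segment, phaseIdx, config) {
  # which heads carry a loss in a given segment
  if (segment == "main") {
    switch(phaseIdx,
           list(heads = "d1", kinds = "bce"),
           list(heads = "d2", kinds = config$phase2$lossKind),
           list(heads = "fusion", kinds = config$phase3$lossKind))
  } else {
    # fine-tune: sum the losses of all heads trained so far
    if (phaseIdx == 2)
      list(heads = c("d1", "d2"), kinds = c("bce", config$phase2$lossKind))
    else
      list(heads = c("d1", "d2", "fusion"),
           kinds = c("bce", config$phase2$lossKind, config$phase3$lossKind))
  }
}

branchesFor <- function(heads) {
  if ("fusion" %in% heads) c("d1", "d2", "fusion")
  else unique(c(heads))
}

itemLoss <- function(model, item, heads, kinds, config, mode,
                     withGrads = FALSE,
                     groups = c("encoder", "decoder1", "decoder2",
                                "fusion")) {
  branches <- branchesFor(heads)
  fw <- dbfuForwardFull(model, item$input, mode = mode,
                        withCache = withGrads, branches = branches)
  mask <- if (config$lossInFov) as.numeric(item$fov) else NULL
  y <- as.numeric(item$label)
  total <- 0; dz <- list(d1 = NULL, d2 = NULL, fusion = NULL)
  for (i in seq_along(heads)) {
    h <- heads[i]; kind <- kinds[i]
    z <- switch(h, d1 = fw$z1, d2 = fw$z2, fusion = fw$zf)
    p <- as.numeric(sigmoidStable(z))
    w <- if (kind == "weighted_bce") as.numeric(item$weights) else NULL
    lg <- lossAndGrad(kind, p, y, weights = w, mask = mask)
    total <- total + lg$value
    dz[[h]] <- matrix(lg$dz, length(lg$dz), 1L)
  }
  if (!withGrads) return(list(loss = total))
  grads <- dbfuBackward(model, fw, dz1 = dz$d1, dz2 = dz$d2,
                        dzf = dz$fusion, groups = groups)
  list(loss = total, grads = grads)
}

validationLoss <- function(model, valItems, heads, kinds, config) {
  mean(vapply(valItems, function(it)
    itemLoss(model, it, heads, kinds, config, mode = "eval")$loss,
    numeric(1)))
}

# --- segment / staged training --------------------------------------------

trainSegment <- function(model, trainSamples, valItems, phase, phaseIdx,
                         segment, config, history, stepSeed) {
  spec <- headLossSpec(segment, phaseIdx, config)
  groups <- if (segment == "main") phase$trainableGroups
            else intersect(c("encoder", "decoder1", "decoder2", "fusion"),
                           names(model$params))
  epochs <- if (segment == "main") phase$epochs else phase$fineTuneEpochs
  if (epochs < 1) return(list(model = model, history = history))
  vel <- list()
  nTrain <- length(trainSamples)
  best <- list(loss = Inf, params = NULL)
  stepCount <- 0L
  totalSteps <- epochs * nTrain
  for (ep in seq_len(epochs)) {
    ord <- base::sample.int(nTrain)
    batchGrads <- NULL; batchLoss <- 0; inBatch <- 0L
    for (j in seq_along(ord)) {
      lr <- if (segment == "main")
        lrAt(phase, stepCount / totalSteps) else phase$fineTuneLr
      s <- trainSamples[[ord[j]]]
      item <- prepareTrainItem(s, config, model,
                               augmentSeed = deriveSeed(stepSeed,
                                                        stepCount + 1L))
      r <- itemLoss(model, item, spec$heads, spec$kinds, config,
                    mode = "train", withGrads = TRUE, groups = groups)
      batchGrads <- addGrads(batchGrads, r$grads)
      batchLoss <- batchLoss + r$loss
      inBatch <- inBatch + 1L
      stepCount <- stepCount + 1L
      if (inBatch == phase$batchSize || j == nTrain) {
        upd <- sgdUpdate(model$params, scaleGrads(batchGrads, 1 / inBatch),
                         vel, lr, groups = groups)
        model$params <- upd$params; vel <- upd$vel
        history$steps[[length(history$steps) + 1L]] <-
          data.frame(phase = phaseIdx, segment = segment, epoch = ep,
                     step = stepCount, lr = lr,
                     loss = batchLoss / inBatch)
        batchGrads <- NULL; batchLoss <- 0; inBatch <- 0L
      }
    }
    vloss <- validationLoss(model, valItems, spec$heads, spec$kinds, config)
    history$epochs[[length(history$epochs) + 1L]] <-
      data.frame(phase = phaseIdx, segment = segment, epoch = ep,
                 valLoss = vloss)
    if (config$selectBest && vloss < best$loss)
      best <- list(loss = vloss, params = model$params)
  }
  if (config$selectBest && !is.null(best$params))
    model$params <- best$params
  list(model = model, history = history)
}

#' Run the staged training procedure
#'
#' Executes the three phases (five segments) described in
#' [stagedTrainConfig()]: decoder-1 training, hard-example-weighted
#' decoder-2 training with the encoder frozen, full fine-tune, fusion
#' training with everything else frozen, full fine-tune. Fresh parameter
#' groups are he-normal re-initialized at their phase start; per-epoch
#' validation loss drives model selection within each segment.
#'
#' @param model a model from [buildDbfuNet()].
#' @param dataset list of [FundusSample-class] training samples.
#' @param config a [stagedTrainConfig()].
#' @return list with `model` (trained), `history` (data frames `steps`
#'   and `epochs`), and `split` (the train/validation partition).
#' @export
runStagedTraining <- function(model, dataset, config = stagedTrainConfig()) {
  if (length(dataset) == 0) stop("empty dataset")
  if (model$spec$singleBranch)
    stop("staged training requires the double-branch model")
  sp <- splitTrainValidation(dataset, config$validationFraction,
                             seed = config$seed)
  # validation items are preprocessed once, never augmented
  valItems <- lapply(sp$validation, prepareTrainItem, config = config,
                     model = model, augmentSeed = NULL)
  history <- list(steps = list(), epochs = list())
  run <- function(model, history, phase, phaseIdx, segment, stream) {
    withSeed(deriveSeed(config$seed, stream), {
      trainSegment(model, sp$train, valItems, phase, phaseIdx, segment,
                   config, history, stepSeed = deriveSeed(config$seed,
                                                          stream + 50L))
    })
  }
  # phase 1: encoder + decoder1, plain cross-entropy
  r <- run(model, history, config$phase1, 1L, "main", 1L)
  # phase 2: fresh decoder2, encoder frozen, hard-weighted loss
  r$model$params$decoder2 <- withSeed(deriveSeed(config$seed, 11L),
                                      initDecoder(r$model$spec))
  r <- run(r$model, r$history, config$phase2, 2L, "main", 2L)
  if (!is.null(config$phase2$fineTuneLr))
    r <- run(r$model, r$history, config$phase2, 2L, "finetune", 3L)
  # phase 3: fresh fusion, all else frozen
  r$model$params$fusion <- withSeed(deriveSeed(config$seed, 12L),
                                    initFusion(r$model$spec))
  r <- run(r$model, r$history, config$phase3, 3L, "main", 4L)
  if (!is.null(config$phase3$fineTuneLr))
    r <- run(r$model, r$history, config$phase3, 3L, "finetune", 5L)
  history <- r$history
  list(model = r$model,
       history = list(steps = do.call(rbind, history$steps),
                      epochs = do.call(rbind, history$epochs)),
       split = sp)
}

#' Desk-scale staged training configuration
#'
#' A scaled-down instantiation of the staged schedule for the synthetic
#' CPU testbed (reduced model, 128 px images, tens of samples). Relative
#' to the full-benchmark defaults in [stagedTrainConfig()], segments are
#' shorter and learning rates larger: with only a few dozen minibatch
#' updates per epoch (versus thousands on an augmented clinical training
#' set) the optimizer needs bigger steps to traverse the same loss
#' terrain, and the 1/3-decay schedule then brings it down within each
#' segment. Fine-tune rates are scaled by the same factor as the base
#' rate. See the methods vignette for the sizing rationale.
#'
#' @param seed master seed (see [stagedTrainConfig()]).
#' @return a `stagedTrainConfig` list.
#' @export
scaledStagedConfig <- function(seed = 1L) {
  stagedTrainConfig(
    phase1 = phaseConfig(c("encoder", "decoder1"), "bce",
                         baseLr = 4e-2, epochs = 8L),
    phase2 = phaseConfig("decoder2", "weighted_bce", baseLr = 4e-2,
                         epochs = 6L, fineTuneLr = 3e-3,
                         fineTuneEpochs = 3L),
    phase3 = phaseConfig("fusion", "bce", baseLr = 4e-2, epochs = 5L,
                         fineTuneLr = 3e-3, fineTuneEpochs = 2L),
    seed = seed)
}

#' Decoder-threshold comparison experiment
#'
#' Trains the double-branch model on a small synthetic dataset and
#' returns the validation-optimal gray thresholds of both decoder heads.
#' The hard-example-weighted decoder (decoder 2) over-calls vessel-like
#' pixels, so its F1-optimal threshold tends to sit at or above
#' decoder 1's -- the signature of hard-example weighting. Uses a
#' shortened two-phase-focused schedule; the fusion phase is kept minimal
#' because only decoder heads are compared.
#'
#' @param seed experiment seed.
#' @param nSamples synthetic training samples (default 16).
#' @param size image side in px (default 128).
#' @return list with integer `thresholdDecoder1`, `thresholdDecoder2`
#'   and the trained run.
#' @export
decoderThresholdExperiment <- function(seed, nSamples = 16L, size = 128L) {
  dataset <- generateFundusDataset(
    nSamples, synthConfig(height = size, width = size,
                          seed = deriveSeed(seed, 21L)))
  tc <- stagedTrainConfig(
    phase1 = phaseConfig(c("encoder", "decoder1"), "bce",
                         baseLr = 4e-2, epochs = 4L),
    phase2 = phaseConfig("decoder2", "weighted_bce", baseLr = 4e-2,
                         epochs = 4L, fineTuneLr = NULL,
                         fineTuneEpochs = 0L),
    phase3 = phaseConfig("fusion", "bce", baseLr = 4e-2, epochs = 1L,
                         fineTuneLr = NULL, fineTuneEpochs = 0L),
    seed = seed)
  model <- buildDbfuNet(modelSpec(depth = 3L, baseChannels = 8L),
                        seed = deriveSeed(seed, 22L))
  r <- runStagedTraining(model, dataset, tc)
  val <- r$split$validation
  labs <- lapply(val, vesselLabel); fovs <- lapply(val, fovMask)
  thr <- function(head) {
    maps <- lapply(predictSamples(r$model, val, head = head), toGrayMap)
    selectThreshold(maps, labs, fovs)
  }
  list(thresholdDecoder1 = thr("decoder1"),
       thresholdDecoder2 = thr("decoder2"), run = r)
}
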