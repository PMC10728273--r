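# Adversarial training loop, case-level split, full-volume inference by slice
# reassembly, and volume-level evaluation.

#' Deterministic case-level train/validation split
#'
#' @param caseIds character or integer vector of case identifiers (>= 2).
#' @param ratio training fraction (0.8 gives the 8:2 split).
#' @param seed RNG seed.
#' @return List with `train` and `validation`; disjoint, exhaustive, train
#'   size `round(ratio * n)`.
#' @export
splitCases <- function(caseIds, ratio = 0.8, seed = 1L) {
  n <- length(caseIds)
  if (n < 2L) stop("need at least 2 cases to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  withSeed(seed, {
    perm <- sample(n)
    k <- round(ratio * n)
    list(train = caseIds[sort(perm[seq_len(k)])],
         validation = caseIds[sort(perm[setdiff(seq_len(n), seq_len(k))])])
  })
}

# Stack channels-first pairs list(x = (4,S,S), y = (3,S,S)) into (S,S,C,N).
stackPairs <- function(pairs) {
  n <- length(pairs)
  dx <- dim(pairs[[1]]$x); s <- dx[2]
  X <- array(0, c(s, s, dx[1], n))
  Y <- array(0, c(s, s, dim(pairs[[1]]$y)[1], n))
  for (i in seq_len(n)) {
    X[, , , i] <- aperm(pairs[[i]]$x, c(2, 3, 1))
    Y[, , , i] <- aperm(pairs[[i]]$y, c(2, 3, 1))
  }
  list(x = X, y = Y)
}

subBatch <- function(a, idx) a[, , , idx, drop = FALSE]

# Mean per-region slice-level Dice of thresholded predictions (H,W,3,N).
sliceDice <- function(prob, truth, threshold = 0.5) {
  n <- dim(prob)[4]
  d <- matrix(0, n, 3)
  for (i in seq_len(n))
    for (r in 1:3)
      d[i, r] <- diceFromMasks(prob[, , r, i] > threshold,
                               truth[, , r, i] > 0.5)
  colMeans(d)
}

validationDice <- function(seg, X, Y, batchSize = 16L) {
  n <- dim(X)[4]
  acc <- matrix(0, 0, 3)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1)
    out <- forwardSegmenter(seg, subBatch(X, idx), train = FALSE)$out
    nres <- length(idx)
    d <- matrix(0, nres, 3)
    for (i in seq_len(nres))
      for (r in 1:3)
        d[i, r] <- diceFromMasks(out[, , r, i] > 0.5, Y[, , r, idx[i]] > 0.5)
    acc <- rbind(acc, d)
  }
  colMeans(acc)
}

#' Adversarial training of the segmenter against the multiscale critic
#'
#' Per batch, the critic first ascends the multiscale L1 feature loss between
#' its features of `maskedPair(image, S(image))` and of
#' `maskedPair(image, truth)` (maximizing over its parameters), then the
#' segmenter descends the same loss through the updated critic. Both networks
#' use Adam with betas (0.5, 0.999) at the configured learning rate. The run
#' is fully seeded: parameter initialization, shuffling and batching derive
#' from `cfg@seed` and the model config seeds.
#'
#' @param cfg A [TrainConfig-class].
#' @param trainPairs list of `list(x = (4,S,S), y = (3,S,S))` pairs (e.g.
#'   `preprocessCase(...)$pairs`).
#' @param valPairs like `trainPairs`, used for per-epoch validation Dice.
#' @param segCfg A [SegmenterConfig-class] (input size must match S).
#' @param criticCfg A [CriticConfig-class]; `inChannels` must be 12.
#' @return A `TrainResult` list: `segLoss`, `criticLoss` (per-epoch means),
#'   `valDice` (epochs x 3 matrix, columns WT/TC/ET), `valMean`,
#'   `bestCheckpoint` (path or NULL), `segmenter`, `critic`.
#' @export
trainModel <- function(cfg, trainPairs, valPairs, segCfg, criticCfg) {
  validObject(cfg)
  if (length(trainPairs) == 0L) stop("no training data")
  seg <- buildSegmenter(segCfg)
  critic <- buildCritic(criticCfg)
  tr <- stackPairs(trainPairs)
  va <- if (length(valPairs)) stackPairs(valPairs) else NULL
  n <- dim(tr$x)[4]
  optS <- adamInit(); optC <- adamInit()
  lr <- cfg@learningRate
  segLoss <- criticLoss <- numeric(cfg@epochs)
  valDice <- matrix(NA_real_, cfg@epochs, 3,
                    dimnames = list(NULL, c("wt", "tc", "et")))
  best <- -Inf; bestPath <- NULL
  logLine <- function(s) {
    message(s)
    if (nzchar(cfg@logPath)) cat(s, "\n", file = cfg@logPath, append = TRUE)
  }
  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample(n)
      bl_s <- bl_c <- numeric(0)
      for (start in seq(1, n, by = cfg@batchSize)) {
        idx <- ord[start:min(n, start + cfg@batchSize - 1)]
        xb <- subBatch(tr$x, idx); yb <- subBatch(tr$y, idx)
        sf <- forwardSegmenter(seg, xb, train = TRUE, withCache = TRUE)
        seg$run <- sf$run
        a <- maskedPairHWCN(xb, sf$out)
        b <- maskedPairHWCN(xb, yb)
        # critic ascent
        for (cstep in seq_len(cfg@alternation)) {
          fa <- forwardCritic(critic, a, train = TRUE, withCache = TRUE)
          critic$run <- fa$run
          fb <- forwardCritic(critic, b, train = TRUE, withCache = TRUE)
          critic$run <- fb$run
          lC <- multiscaleL1(fa$features, fb$features)$loss
          dfa <- multiscaleL1GradA(fa$features, fb$features)
          dfb <- lapply(dfa, function(g) -g)
          gC <- addGrads(backwardCritic(critic, fa$cache, dfa)$grads,
                         backwardCritic(critic, fb$cache, dfb)$grads)
          up <- adamStep(critic$params, gC, optC, lr, maximize = TRUE)
          critic$params <- up$params; optC <- up$opt
        }
        # segmenter descent through the updated critic
        fa <- forwardCritic(critic, a, train = TRUE, withCache = TRUE)
        critic$run <- fa$run
        fb <- forwardCritic(critic, b, train = TRUE, withCache = FALSE)
        critic$run <- fb$run
        lS <- multiscaleL1(fa$features, fb$features)$loss
        if (!is.finite(lS) || !is.finite(lC))
          stop(sprintf("non-finite loss at epoch %d (segmenter %g, critic %g)",
                       epoch, lS, lC))
        dfa <- multiscaleL1GradA(fa$features, fb$features)
        da <- backwardCritic(critic, fa$cache, dfa, needDx = TRUE)$dx
        dmask <- maskedPairBwdMask(xb, da)
        gS <- backwardSegmenter(seg, sf$cache, dmask)$grads
        up <- adamStep(seg$params, gS, optS, lr)
        seg$params <- up$params; optS <- up$opt
        bl_s <- c(bl_s, lS); bl_c <- c(bl_c, lC)
      }
      segLoss[epoch] <- mean(bl_s); criticLoss[epoch] <- mean(bl_c)
      if (!is.null(va)) {
        valDice[epoch, ] <- validationDice(seg, va$x, va$y, cfg@batchSize)
        vm <- mean(valDice[epoch, ])
        if (vm > best) {
          best <- vm
          if (nzchar(cfg@checkpointDir)) {
            dir.create(cfg@checkpointDir, recursive = TRUE, showWarnings = FALSE)
            bestPath <- file.path(cfg@checkpointDir, "best.rds")
            saveModel(list(segmenter = seg, critic = critic, epoch = epoch), bestPath)
          }
        }
      }
      logLine(sprintf(
        "epoch=%d lossS=%.6f lossC=%.6f valWT=%.4f valTC=%.4f valET=%.4f seed=%d",
        epoch, segLoss[epoch], criticLoss[epoch], valDice[epoch, 1],
        valDice[epoch, 2], valDice[epoch, 3], cfg@seed))
    }
  })
  structure(list(segLoss = segLoss, criticLoss = criticLoss,
                 valDice = valDice, valMean = rowMeans(valDice),
                 bestCheckpoint = bestPath, segmenter = seg, critic = critic),
            class = "TrainResult")
}

#' Segment a full case by slice reassembly
#'
#' Preprocesses every axial slice (no lesion-free-slice dropping at
#' inference), runs the segmenter, thresholds the region probabilities at
#' 0.5, maps the masks back through the resize and crop to native slice
#' geometry, converts regions to labels (4 where ET; 1 where TC and not ET;
#' 2 where WT and not TC; 0 elsewhere) and stacks the slices into a volume.
#'
#' @param model a segmenter model (from [buildSegmenter()] or a train result).
#' @param case A [MultimodalCase-class].
#' @param prepCfg settings from [preprocessConfig()]; `targetSize` must match
#'   the model's input size.
#' @param batchSize forward batch size.
#' @return Integer label volume of the same shape as the case's volumes.
#' @export
segmentCase <- function(model, case, prepCfg = preprocessConfig(),
                        batchSize = 16L) {
  if (prepCfg$targetSize != model$cfg@inputSize)
    stop("prepCfg$targetSize must equal the model input size")
  prepCfg$dropEmpty <- FALSE
  pp <- preprocessCase(case, prepCfg)
  shape <- dim(case@seg)
  st <- stackPairs(pp$pairs)
  n <- dim(st$x)[4]
  prob <- array(0, c(prepCfg$targetSize, prepCfg$targetSize, 3, n))
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1)
    prob[, , , idx] <- forwardSegmenter(model, subBatch(st$x, idx),
                                        train = FALSE)$out
  }
  out <- array(0L, shape)
  for (i in seq_len(n)) {
    p <- pp$pairs[[i]]
    lab <- labelsFromMasks(list(wt = prob[, , 1, i] > 0.5,
                                tc = prob[, , 2, i] > 0.5,
                                et = prob[, , 3, i] > 0.5))
    box <- p$crop
    side <- max(box$rows[2] - box$rows[1], box$cols[2] - box$cols[1])
    labSide <- if (side == nrow(lab)) lab else nearestResize(lab, side)
    sl <- matrix(0L, shape[1], shape[2])
    sl[(box$rows[1] + 1):box$rows[2], (box$cols[1] + 1):box$cols[2]] <-
      labSide[seq_len(box$rows[2] - box$rows[1]),
              seq_len(box$cols[2] - box$cols[1])]
    out[, , p$sliceIndex + 1L] <- sl
  }
  out
}

#' Volume-level evaluation report
#'
#' Per-case, per-region Dice (WT/TC/ET via the standard label composition),
#' region means and their grand average.
#'
#' @param predictions list of predicted label volumes.
#' @param truths list of reference label volumes, same length and shapes.
#' @param csvPath optional CSV export path.
#' @return An `EvalReport` list: `perCase` (data.frame), `regionMeans`,
#'   `average`.
#' @export
evaluateSegmentations <- function(predictions, truths, csvPath = NULL) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must be paired")
  rows <- lapply(seq_along(predictions), function(i) {
    if (!identical(dim(predictions[[i]]), dim(truths[[i]])))
      stop("shape mismatch for case ", i)
    mp <- regionMasks(predictions[[i]])
    mt <- regionMasks(truths[[i]])
    data.frame(case = if (!is.null(names(predictions)))
                 names(predictions)[i] else as.character(i),
               wt = diceFromMasks(mp$wt, mt$wt),
               tc = diceFromMasks(mp$tc, mt$tc),
               et = diceFromMasks(mp$et, mt$et))
  })
  perCase <- do.call(rbind, rows)
  regionMeans <- colMeans(perCase[, c("wt", "tc", "et")])
  report <- structure(list(perCase = perCase, regionMeans = regionMeans,
                           average = mean(regionMeans)),
                      class = "EvalReport")
  if (!is.null(csvPath)) {
    tab <- rbind(perCase,
                 data.frame(case = "mean", wt = regionMeans["wt"],
                            tc = regionMeans["tc"], et = regionMeans["et"]))
    tab$average <- rowMeans(tab[, c("wt", "tc", "et")])
    utils::write.csv(tab, csvPath, row.names = FALSE)
  }
  report
}
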