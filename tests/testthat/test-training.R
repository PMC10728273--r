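tinyTrainSetup <- function(nTrain = 8, nVal = 4, size = 32L, seed = 1) {
  set.seed(seed)
  mk <- function(n) lapply(seq_len(n), function(i) {
    # blob target with correlated input channels, cheap stand-in for slices
    cc <- runif(2, 10, size - 10)
    d <- sqrt(outer((1:size - cc[1])^2, (1:size - cc[2])^2, `+`))
    wt <- d <= 8; tc <- d <= 5; et <- d <= 3
    x <- array(0, c(4L, size, size))
    for (m in 1:4) x[m, , ] <- wt * (0.5 + 0.25 * m) + matrix(rnorm(size^2, sd = 0.1), size, size)
    y <- array(0L, c(3L, size, size))
    y[1, , ] <- wt; y[2, , ] <- tc; y[3, , ] <- et
    list(x = x, y = y)
  })
  list(train = mk(nTrain), val = mk(nVal))
}

segCfg32 <- segmenterConfig(inputSize = 32L, baseWidth = 8L, seReduction = 4L,
                            seed = 2L)
criticCfgSmall <- criticConfig(widths = c(8L, 16L, 24L, 32L), seed = 3L)

test_that("case splitting is disjoint, exhaustive and deterministic", {
  ids <- sprintf("case%02d", 1:10)
  sp <- splitCases(ids, 0.8, seed = 4)
  expect_length(sp$train, 8L)
  expect_length(sp$validation, 2L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_identical(sp, splitCases(ids, 0.8, seed = 4))
  expect_false(identical(sp, splitCases(ids, 0.8, seed = 5)))
  expect_error(splitCases("one", 0.8, 1), "at least 2")
})

test_that("one training epoch completes with finite logged losses", {
  d <- tinyTrainSetup()
  res <- trainModel(trainConfig(epochs = 1L, batchSize = 4L, seed = 1L),
                    d$train, d$val, segCfg32, criticCfgSmall)
  expect_true(is.finite(res$segLoss[1]))
  expect_true(is.finite(res$criticLoss[1]))
  expect_true(all(res$valDice[1, ] >= 0 & res$valDice[1, ] <= 1))
})

test_that("training is reproducible: identical losses for identical seeds", {
  d <- tinyTrainSetup()
  cfg <- trainConfig(epochs = 1L, batchSize = 4L, seed = 9L)
  r1 <- trainModel(cfg, d$train, d$val, segCfg32, criticCfgSmall)
  r2 <- trainModel(cfg, d$train, d$val, segCfg32, criticCfgSmall)
  expect_identical(r1$segLoss, r2$segLoss)
  expect_identical(r1$criticLoss, r2$criticLoss)
  expect_identical(r1$valDice, r2$valDice)
})

test_that("the segmenter descends the loss under a frozen identity-feature critic", {
  d <- tinyTrainSetup(nTrain = 1, nVal = 0)
  st <- MRSegGAN:::stackPairs(d$train)
  seg <- buildSegmenter(segCfg32)
  opt <- MRSegGAN:::adamInit()
  b <- MRSegGAN:::maskedPairHWCN(st$x, st$y)
  losses <- numeric(50)
  for (i in 1:50) {
    f <- forwardSegmenter(seg, st$x, train = TRUE, withCache = TRUE)
    seg$run <- f$run
    a <- MRSegGAN:::maskedPairHWCN(st$x, f$out)
    losses[i] <- multiscaleL1(list(a), list(b))$loss
    dfa <- MRSegGAN:::multiscaleL1GradA(list(a), list(b))
    dmask <- MRSegGAN:::maskedPairBwdMask(st$x, dfa[[1]])
    g <- MRSegGAN:::backwardSegmenter(seg, f$cache, dmask)$grads
    up <- MRSegGAN:::adamStep(seg$params, g, opt, 2e-4)
    seg$params <- up$params; opt <- up$opt
  }
  expect_lt(losses[50], losses[1])
})

test_that("checkpoints round-trip to identical validation Dice", {
  d <- tinyTrainSetup()
  ckdir <- tempfile("ck")
  res <- trainModel(trainConfig(epochs = 1L, batchSize = 4L, seed = 2L,
                                checkpointDir = ckdir),
                    d$train, d$val, segCfg32, criticCfgSmall)
  expect_true(file.exists(res$bestCheckpoint))
  va <- MRSegGAN:::stackPairs(d$val)
  d1 <- MRSegGAN:::validationDice(res$segmenter, va$x, va$y)
  restored <- loadModel(res$bestCheckpoint)$segmenter
  d2 <- MRSegGAN:::validationDice(restored, va$x, va$y)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("full-volume inference reassembles slices with valid labels", {
  case <- generateCase(phantomConfig(volumeShape = c(32L, 32L, 12L)), seed = 3)
  seg <- buildSegmenter(segCfg32)
  prep <- preprocessConfig(targetSize = 32L, crop = FALSE)
  pred <- segmentCase(seg, case, prep)
  expect_identical(dim(pred), dim(segVolume(case)))
  expect_true(all(unique(as.vector(pred)) %in% c(0L, 1L, 2L, 4L)))
  expect_error(segmentCase(seg, case, preprocessConfig(targetSize = 64L)),
               "input size")
})

test_that("feeding truth region masks through label inversion reproduces seg", {
  case <- generateCase(phantomConfig(volumeShape = c(24L, 24L, 10L)), seed = 5)
  seg <- segVolume(case)
  expect_identical(labelsFromMasks(regionMasks(seg)), seg)
})

test_that("evaluation reports per-case and aggregate region Dice", {
  set.seed(7)
  truths <- lapply(1:3, function(i)
    segVolume(generateCase(phantomConfig(volumeShape = c(20L, 20L, 8L)), seed = i)))
  rep1 <- evaluateSegmentations(truths, truths)
  expect_true(all(unlist(rep1$perCase[, c("wt", "tc", "et")]) == 1))
  expect_identical(rep1$average, 1)
  blanks <- lapply(truths, function(t) array(0L, dim(t)))
  rep0 <- evaluateSegmentations(blanks, truths)
  expect_true(all(unlist(rep0$perCase[, c("wt", "tc", "et")]) == 0))
  # composed oracle on one random pair
  pred <- truths[[1]]
  pred[sample(length(pred), 50)] <- 4L
  r <- evaluateSegmentations(list(pred), list(truths[[1]]))
  mp <- regionMasks(pred); mt <- regionMasks(truths[[1]])
  for (reg in c("wt", "tc", "et")) {
    cc <- bruteConfusion(mp[[reg]], mt[[reg]])
    expect_equal(r$perCase[[reg]][1], 2 * cc$tp / (cc$fp + 2 * cc$tp + cc$fn))
  }
  csv <- tempfile(fileext = ".csv")
  evaluateSegmentations(list(pred), list(truths[[1]]), csvPath = csv)
  expect_true(file.exists(csv))
  tab <- utils::read.csv(csv)
  expect_identical(names(tab), c("case", "wt", "tc", "et", "average"))
  expect_error(evaluateSegmentations(truths, truths[1:2]), "paired")
})
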