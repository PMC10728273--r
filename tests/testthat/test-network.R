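smallSegCfg <- function(...)
  segmenterConfig(inputSize = 32L, baseWidth = 8L, seReduction = 4L, seed = 5L, ...)

test_that("residual unit specs follow the three published arrangements", {
  v3 <- buildResidualUnit(3, 64, 64)
  expect_identical(tail(v3$layers, 1), "add")
  expect_identical(v3$shortcut, "identity")
  v2 <- buildResidualUnit(2, 64, 128)
  expect_identical(tail(v2$layers, 2), c("add", "relu"))
  expect_identical(v2$shortcut, "projection1x1")
  v1 <- buildResidualUnit(1, 32, 32)
  expect_identical(v1$layers[1:3], c("bn", "relu", "conv3x3"))
  expect_error(buildResidualUnit(4, 8, 8), "unknown")
})

test_that("a zeroed residual unit with matching channels is the identity", {
  for (variant in 1:3) {
    p <- MRSegGAN:::makeUnitParams(6L, 6L, variant)
    p$conv1$w[] <- 0; p$conv2$w[] <- 0
    run <- list(bn1 = MRSegGAN:::newBnRun(6L), bn2 = MRSegGAN:::newBnRun(6L))
    x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
    y <- MRSegGAN:::unitFwd(x, p, run, variant, train = TRUE)$y
    if (variant == 2L) expect_equal(y, MRSegGAN:::reluFwd(x), tolerance = 1e-12)
    else expect_equal(y, x, tolerance = 1e-12)
    expect_identical(dim(y), dim(x))
  }
})

test_that("the SE gate stays in (0,1) and zero-initialized weights halve the input", {
  expect_error(buildSEUnit(8, 16), "reduction")
  spec <- buildSEUnit(64, 16)
  expect_identical(spec$bottleneck, 4L)
  set.seed(1)
  x <- array(rnorm(6 * 6 * 8 * 3), c(6, 6, 8, 3))
  w1 <- matrix(rnorm(2 * 8), 2, 8); w2 <- matrix(rnorm(8 * 2), 8, 2)
  sf <- MRSegGAN:::seFwd(x, w1, rnorm(2), w2, rnorm(8))
  expect_true(all(sf$cache$g > 0 & sf$cache$g < 1))
  expect_identical(dim(sf$y), dim(x))
  z <- MRSegGAN:::seFwd(x, 0 * w1, numeric(2), 0 * w2, numeric(8))
  expect_equal(z$y, x / 2, tolerance = 1e-12)
})

test_that("the default segmenter passes the 19-convolution census at 9 levels", {
  m <- buildSegmenter(smallSegCfg())
  expect_identical(convLayerCount(m), 19L)
  expect_identical(unitLevelCount(m), 9L)
  mNoSe <- buildSegmenter(smallSegCfg(seEnabled = FALSE))
  expect_identical(convLayerCount(mNoSe), 19L)
  expect_error(buildSegmenter(segmenterConfig(inputSize = 100L)), "divisible")
})

test_that("the encoder halves the spatial side and doubles the width per level", {
  cfg <- smallSegCfg()
  m <- buildSegmenter(cfg)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4, 1))
  f <- forwardSegmenter(m, x, withCache = TRUE)
  expect_identical(m$arch$encWidths, 8L * c(1L, 2L, 4L, 8L))
  for (k in 1:4) {
    d <- f$cache[[paste0("pool", k)]]$dim
    expect_identical(d[1], as.integer(32 / 2^(k - 1)))
    expect_identical(d[3], as.integer(8 * 2^(k - 1)))
  }
  expect_identical(dim(f$bridge), c(2L, 2L, 128L, 1L))
  expect_identical(dim(f$out), c(32L, 32L, 3L, 1L))
  expect_true(all(f$out > 0 & f$out < 1))
})

test_that("parameter initialization is deterministic under a fixed seed", {
  a <- buildSegmenter(smallSegCfg())
  b <- buildSegmenter(smallSegCfg())
  expect_identical(MRSegGAN:::flattenLeaves(a$params),
                   MRSegGAN:::flattenLeaves(b$params))
  ca <- buildCritic(criticConfig(widths = c(8L, 16L, 24L, 32L), seed = 3L))
  cb <- buildCritic(criticConfig(widths = c(8L, 16L, 24L, 32L), seed = 3L))
  expect_identical(MRSegGAN:::flattenLeaves(ca$params),
                   MRSegGAN:::flattenLeaves(cb$params))
})

test_that("the critic exposes L stride-2 feature maps", {
  cr <- buildCritic(criticConfig(widths = c(8L, 16L, 24L, 32L)))
  expect_identical(convLayerCount(cr), 4L)
  x <- array(rnorm(32 * 32 * 12 * 2), c(32, 32, 12, 2))
  f <- forwardCritic(cr, x)
  expect_length(f$features, 4L)
  sides <- vapply(f$features, function(z) dim(z)[1], integer(1))
  expect_identical(sides, c(16L, 8L, 4L, 2L))
  widths <- vapply(f$features, function(z) dim(z)[3], integer(1))
  expect_identical(widths, c(8L, 16L, 24L, 32L))
})

test_that("every trainable parameter receives a finite gradient", {
  m <- buildSegmenter(smallSegCfg())
  set.seed(2)
  x <- array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  f <- forwardSegmenter(m, x, train = TRUE, withCache = TRUE)
  dout <- array(rnorm(length(f$out)), dim(f$out))
  g <- MRSegGAN:::backwardSegmenter(m, f$cache, dout)$grads
  gf <- MRSegGAN:::flattenLeaves(g)
  pf <- MRSegGAN:::flattenLeaves(m$params)
  expect_setequal(names(gf), names(pf))
  expect_true(all(vapply(gf, function(z) all(is.finite(z)), logical(1))))
})

test_that("channels-first single slices are accepted and checkpoints round-trip", {
  m <- buildSegmenter(smallSegCfg())
  x <- array(rnorm(4 * 32 * 32), c(4, 32, 32))
  out <- forwardSegmenter(m, x)$out
  expect_identical(dim(out), c(32L, 32L, 3L, 1L))
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  out2 <- forwardSegmenter(m2, x)$out
  expect_identical(out, out2)
})
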