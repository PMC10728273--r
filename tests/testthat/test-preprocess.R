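test_that("z-score normalization zeroes the masked mean and unitizes the sd", {
  set.seed(1)
  v <- array(rnorm(24^3, 50, 7), c(24, 24, 24))
  mask <- array(runif(24^3) > 0.4, c(24, 24, 24))
  out <- zscoreNormalize(v, mask)
  n <- sum(mask)
  expect_lt(abs(mean(out[mask])), 1e-6)
  popSd <- sqrt(mean((out[mask] - mean(out[mask]))^2))
  expect_lt(abs(popSd - 1), 1e-6)
  expect_true(all(out[!mask] == 0))
})

test_that("normalization is affine-invariant and idempotent", {
  set.seed(2)
  v <- array(rnorm(10^3), c(10, 10, 10))
  mask <- array(TRUE, dim(v))
  a <- zscoreNormalize(3.7 * v + 11, mask)
  b <- zscoreNormalize(v, mask)
  expect_equal(a, b, tolerance = 1e-10)
  expect_lt(max(abs(zscoreNormalize(b, mask) - b)), 1e-5)
})

test_that("constant or empty brain regions are rejected", {
  v <- array(5, c(4, 4, 4))
  expect_error(zscoreNormalize(v, array(TRUE, dim(v))), "degenerate")
  expect_error(zscoreNormalize(array(0, c(4, 4, 4))), "empty")
})

test_that("axial slicing follows the third axis and drop-empty matches a brute scan", {
  case <- generateCase(tinyPhantomConfig(c(32L, 32L, 21L)), seed = 9)
  all_ <- axialSlices(case, dropEmpty = FALSE)
  expect_length(all_, 21L)
  expect_identical(vapply(all_, function(r) r@sliceIndex, integer(1)), 0:20)
  expect_identical(all_[[7]]@images$t2, modalityVolume(case, "t2")[, , 7])
  kept <- axialSlices(case, dropEmpty = TRUE)
  bruteKeep <- 0L
  for (k in seq_len(dim(segVolume(case))[3]))
    if (any(segVolume(case)[, , k] != 0L)) bruteKeep <- bruteKeep + 1L
  expect_length(kept, bruteKeep)
  empty <- case
  empty@seg <- array(0L, dim(case@seg))
  expect_length(axialSlices(empty, dropEmpty = TRUE), 0L)
})

test_that("slicing partitions the volume: stacking slices reconstructs it", {
  case <- generateCase(tinyPhantomConfig(c(20L, 20L, 9L)), seed = 4)
  recs <- axialSlices(case, dropEmpty = FALSE)
  rebuilt <- array(0, dim(case@flair))
  for (r in recs) rebuilt[, , r@sliceIndex + 1L] <- r@images$flair
  expect_identical(rebuilt, case@flair)
})

test_that("region composition implements the standard label algebra", {
  seg <- array(4L, c(3, 3))
  m <- regionMasks(seg)
  expect_true(all(m$wt) && all(m$tc) && all(m$et))
  seg <- array(0L, c(3, 3)); seg[2, 2] <- 1L
  m <- regionMasks(seg)
  expect_true(m$wt[2, 2] && m$tc[2, 2] && !m$et[2, 2])
  expect_identical(sum(m$wt), 1L)
  m0 <- regionMasks(array(0L, c(2, 2)))
  expect_false(any(m0$wt) || any(m0$tc) || any(m0$et))
  expect_error(regionMasks(array(3L, c(2, 2))), "3")
})

test_that("label inversion is the exact inverse of region composition", {
  set.seed(5)
  for (i in 1:5) {
    seg <- array(sample(c(0L, 1L, 2L, 4L), 60, replace = TRUE), c(5, 4, 3))
    expect_identical(labelsFromMasks(regionMasks(seg)), seg)
  }
})

test_that("channel assembly fixes the FLAIR/T1/T1c/T2 order", {
  case <- generateCase(tinyPhantomConfig(c(16L, 16L, 8L)), seed = 2)
  rec <- axialSlices(case, dropEmpty = TRUE)[[1]]
  x <- assembleChannels(rec)
  expect_identical(dim(x), c(4L, 16L, 16L))
  expect_identical(x[1, , ], rec@images$flair)
  expect_identical(x[4, , ], rec@images$t2)
  imgs <- rec@images
  imgs$t1c <- NULL
  expect_error(assembleChannels(imgs), "missing modality")
})

test_that("NPY files round-trip arrays exactly", {
  set.seed(3)
  x <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  f <- tempfile(fileext = ".npy")
  npyWrite(x, f, "float64")
  expect_identical(npyRead(f), x)
  xi <- array(sample(0:255, 24, TRUE), c(4, 6))
  npyWrite(xi, f, "uint8")
  expect_identical(npyRead(f), xi)
  x32 <- array(round(rnorm(12), 3), c(3, 4))
  npyWrite(x32, f, "float32")
  expect_equal(npyRead(f), x32, tolerance = 1e-6)
})

test_that("the full pipeline emits (4,S,S)/(3,S,S) pairs, one per lesion slice", {
  case <- generateCase(tinyPhantomConfig(c(48L, 48L, 16L)), seed = 6)
  cfg <- preprocessConfig(targetSize = 160L, dropEmpty = TRUE)
  res <- preprocessCase(case, cfg)
  bruteKeep <- sum(apply(segVolume(case) != 0L, 3, any))
  expect_length(res$pairs, bruteKeep)
  p <- res$pairs[[1]]
  expect_identical(dim(p$x), c(4L, 160L, 160L))
  expect_identical(dim(p$y), c(3L, 160L, 160L))
  for (q in res$pairs) {
    expect_true(all(q$y[3, , ] <= q$y[2, , ]))  # ET within TC
    expect_true(all(q$y[2, , ] <= q$y[1, , ]))  # TC within WT
  }
})

test_that("preprocessing to NPY is byte-identical across runs", {
  case <- generateCase(tinyPhantomConfig(c(32L, 32L, 12L)), seed = 8)
  cfg <- preprocessConfig(targetSize = 64L)
  d1 <- tempfile("prep1"); d2 <- tempfile("prep2")
  preprocessCase(case, cfg, outDir = d1)
  preprocessCase(case, cfg, outDir = d2)
  f1 <- sort(list.files(d1, pattern = "\\.npy$", full.names = TRUE))
  f2 <- sort(list.files(d2, pattern = "\\.npy$", full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_gt(length(f1), 0)
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
})
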