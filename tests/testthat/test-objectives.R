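test_that("confusion counts match the per-pixel loop oracle", {
  set.seed(1)
  pred <- matrix(runif(256) > 0.5, 16, 16)
  truth <- matrix(runif(256) > 0.5, 16, 16)
  cc <- confusionCounts(pred, truth)
  oracle <- bruteConfusion(pred, truth)
  expect_identical(cc$tp, oracle$tp)
  expect_identical(cc$tn, oracle$tn)
  expect_identical(cc$fp, oracle$fp)
  expect_identical(cc$fn, oracle$fn)
  expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 256L)
  same <- confusionCounts(truth, truth)
  expect_identical(same$fp + same$fn, 0L)
  comp <- confusionCounts(!truth, truth)
  expect_identical(comp$tp + comp$tn, 0L)
  expect_error(confusionCounts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape")
})

test_that("Dice follows the confusion formula and the empty-mask conventions", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_identical(diceFromMasks(m, m), 1.0)
  expect_identical(diceFromMasks(m, !m), 0.0)
  expect_equal(dice(structure(list(tp = 50, tn = 0, fp = 10, fn = 30),
                              class = "ConfusionCounts")), 100 / 140)
  none <- matrix(FALSE, 3, 3)
  expect_identical(diceFromMasks(none, none), 1.0)
  expect_identical(diceFromMasks(none, matrix(TRUE, 3, 3)), 0.0)
})

test_that("Dice equals the set formula and is symmetric and order-invariant", {
  set.seed(2)
  for (i in 1:100) {
    a <- matrix(runif(64) > runif(1), 8, 8)
    b <- matrix(runif(64) > runif(1), 8, 8)
    d <- diceFromMasks(a, b)
    setFormula <- if (sum(a) + sum(b) == 0) 1.0 else
      2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(d, setFormula, tolerance = 1e-12)
    expect_identical(d, diceFromMasks(b, a))
    perm <- sample(64)
    expect_identical(d, diceFromMasks(matrix(a[perm], 8, 8),
                                      matrix(b[perm], 8, 8)))
  }
})

test_that("the masked critic input stacks all region-by-modality products", {
  set.seed(3)
  img <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  mask <- array(runif(3 * 6 * 5), c(3, 6, 5))
  mp <- maskedPair(img, mask)
  expect_identical(dim(mp), c(12L, 6L, 5L))
  for (r in 1:3) for (m in 1:4)
    expect_equal(mp[(r - 1) * 4 + m, , ], mask[r, , ] * img[m, , ],
                 tolerance = 1e-15)
  expect_true(all(maskedPair(img, 0 * mask) == 0))
  ones <- maskedPair(img, 0 * mask + 1)
  expect_identical(ones[1, , ], ones[5, , ])  # FLAIR replicated per region
  expect_error(maskedPair(img, array(1, c(3, 4, 4))), "matching")
})

test_that("the multiscale L1 loss is a symmetric scaled mean with a breakdown", {
  set.seed(4)
  a <- lapply(c(8, 4), function(s) array(rnorm(s * s * 2), c(s, s, 2, 1)))
  expect_identical(multiscaleL1(a, a)$loss, 0)
  b <- lapply(a, function(z) z + rnorm(length(z)))
  l1 <- multiscaleL1(a, b); l2 <- multiscaleL1(b, a)
  expect_identical(l1$loss, l2$loss)
  expect_equal(l1$loss, mean(l1$perScale))
  expect_true(all(l1$perScale >= 0))
  one <- list(matrix(0, 2, 2)); oneB <- list(matrix(1, 2, 2))
  expect_identical(multiscaleL1(one, oneB)$loss, 1)
  expect_error(multiscaleL1(a, a[1]), "length")
})

test_that("the multiscale L1 loss satisfies the triangle inequality", {
  set.seed(5)
  mk <- function() lapply(c(6, 3), function(s) array(rnorm(s * s), c(s, s, 1, 1)))
  for (i in 1:10) {
    a <- mk(); b <- mk(); c_ <- mk()
    expect_lte(multiscaleL1(a, c_)$loss,
               multiscaleL1(a, b)$loss + multiscaleL1(b, c_)$loss + 1e-12)
  }
})

test_that("the paired t-test reproduces the closed form on fixed numbers", {
  r <- pairedTTest(c(1, 2, 3), c(2, 4, 6))
  # differences (-1, -2, -3): mean -2, sd 1, t = -2 / (1 / sqrt(3))
  expect_equal(r$statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p.value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
  swapped <- pairedTTest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p.value, r$p.value)
  set.seed(6)
  a <- rnorm(10)
  up <- pairedTTest(a + 1 + rnorm(10, sd = 0.1), a)
  expect_gt(up$statistic, 0)
  expect_error(pairedTTest(a, a + 2), "zero variance")
  expect_error(pairedTTest(1, 2), "equal-length")
})
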