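test_that("the hull of simple configurations is exact", {
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  h <- convexHull(tri)
  expect_identical(nrow(h), 3L)
  expect_setequal(apply(h, 1, paste, collapse = ","),
                  apply(tri, 1, paste, collapse = ","))
  set.seed(1)
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  pts <- rbind(square, matrix(runif(40, 1, 9), ncol = 2))
  h <- convexHull(pts)
  expect_identical(nrow(h), 4L)
  expect_setequal(apply(h, 1, paste, collapse = ","),
                  apply(square, 1, paste, collapse = ","))
  expect_identical(nrow(convexHull(rbind(c(1, 1), c(2, 2), c(3, 3)))), 2L)
  expect_error(convexHull(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("random hulls contain every point and use only input vertices", {
  set.seed(2)
  for (rep in 1:5) {
    pts <- matrix(rnorm(100), ncol = 2)
    h <- convexHull(pts)
    # every hull vertex is an input point
    keys <- apply(round(pts, 10), 1, paste, collapse = ",")
    expect_true(all(apply(round(h, 10), 1, paste, collapse = ",") %in% keys))
    # exhaustive half-plane test: all points on the inner side of each edge
    n <- nrow(h)
    for (i in seq_len(n)) {
      a <- h[i, ]; b <- h[(i %% n) + 1, ]
      cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
               (b[2] - a[2]) * (pts[, 1] - a[1])
      expect_true(all(cross >= -1e-9))
    }
    # agreement with the base-R hull
    ch <- pts[grDevices::chull(pts), , drop = FALSE]
    expect_setequal(apply(round(h, 10), 1, paste, collapse = ","),
                    apply(round(ch, 10), 1, paste, collapse = ","))
  }
})

test_that("minimum-area rectangles of known shapes are exact", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- minAreaRect(sq)
  expect_equal(r$area, 1.0, tolerance = 1e-12)
  expect_equal(r$angle %% 90, 0, tolerance = 1e-9)
  # a 2x1 rectangle rotated by 30 degrees
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rect <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)) %*% t(R)
  r <- minAreaRect(rect)
  expect_equal(r$area, 2.0, tolerance = 1e-6)
  expect_lt(min(abs(r$angle %% 90 - 30), abs(r$angle %% 90 - 60)), 1e-6)
  expect_equal(sort(r$size), c(1, 2), tolerance = 1e-9)
})

test_that("rectangle area matches a dense rotation-scan oracle on random sets", {
  set.seed(3)
  for (rep in 1:30) {
    pts <- matrix(rnorm(2 * sample(5:25, 1), sd = 5), ncol = 2)
    r <- minAreaRect(pts)
    oracle <- rotationScanArea(pts)
    expect_lt(abs(r$area - oracle) / max(oracle, 1e-12), 1e-4)
    bbox <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
    expect_lte(r$area, bbox + 1e-9)
  }
})

test_that("rotating the point set rotates the rectangle without changing area", {
  set.seed(4)
  pts <- matrix(rnorm(40, sd = 3), ncol = 2)
  base <- minAreaRect(pts)
  for (deg in c(17, 45, 73)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    r2 <- minAreaRect(pts %*% t(R))
    expect_equal(r2$area, base$area, tolerance = 1e-6)
  }
})

test_that("degenerate hulls yield zero-area rectangles", {
  expect_equal(minAreaRect(rbind(c(2, 3)))$area, 0)
  seg <- minAreaRect(rbind(c(0, 0), c(3, 4)))
  expect_equal(seg$area, 0)
  expect_equal(max(seg$size), 5, tolerance = 1e-9)
})

test_that("crop boxes cover the strong pixels and fall back to the full image", {
  full <- cropBoxFromEdges(matrix(FALSE, 10, 12), c(10L, 12L))
  expect_identical(full, list(rows = c(0L, 10L), cols = c(0L, 12L)))
  edges <- matrix(FALSE, 20, 20)
  edges[c(5, 15), 5] <- TRUE; edges[c(5, 15), 15] <- TRUE
  box <- cropBoxFromEdges(edges, c(20L, 20L), margin = 0L)
  expect_identical(box, list(rows = c(4L, 15L), cols = c(4L, 15L)))
  set.seed(5)
  for (rep in 1:5) {
    e <- matrix(runif(30 * 30) > 0.95, 30, 30)
    if (!any(e)) next
    b <- cropBoxFromEdges(e, c(30L, 30L), margin = 0L)
    idx <- which(e, arr.ind = TRUE)
    expect_true(all(idx[, 1] > b$rows[1] & idx[, 1] <= b$rows[2] &
                    idx[, 2] > b$cols[1] & idx[, 2] <= b$cols[2]))
  }
})

test_that("crop-and-resize is the identity on the full box and preserves labels", {
  set.seed(6)
  img <- matrix(rnorm(64^2), 64, 64)
  full <- list(rows = c(0L, 64L), cols = c(0L, 64L))
  expect_identical(applyCropResize(img, full, 64L, "intensity"), img)
  lab <- matrix(sample(c(0L, 1L, 2L, 4L), 100, TRUE), 10, 10)
  out <- applyCropResize(lab, list(rows = c(0L, 10L), cols = c(0L, 10L)),
                         24L, "label")
  expect_true(all(out %in% lab))
  expect_error(applyCropResize(img, full, 0L), "size")
})

test_that("nearest-neighbor upscaling expands blocks exactly", {
  pat <- matrix(1:16, 4, 4)
  out <- applyCropResize(pat, list(rows = c(0L, 4L), cols = c(0L, 4L)),
                         8L, "label")
  expected <- pat[rep(1:4, each = 2), rep(1:4, each = 2)]
  expect_identical(out, expected)
})
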