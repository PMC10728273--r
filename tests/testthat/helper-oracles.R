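# Shared fixtures and independent brute-force oracles used across the suite.

tinyPhantomConfig <- function(shape = c(48L, 48L, 32L), ...)
  phantomConfig(volumeShape = shape, ...)

diskImage <- function(n = 64, radius = 15, fg = 1, bg = 0) {
  cc <- (n + 1) / 2
  d <- sqrt(outer((1:n - cc)^2, (1:n - cc)^2, `+`))
  img <- matrix(bg, n, n)
  img[d <= radius] <- fg
  list(img = img, disk = d <= radius, dist = d)
}

# Literal double-integral evaluation of the LBF energy (quadruple loop),
# with the local fit values themselves computed by loops.
bruteLbfEnergy <- function(phi, image, params) {
  eps <- params@epsilon
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  K <- gaussianKernel2d(params@sigma)
  r <- (nrow(K) - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  kAt <- function(xi, xj, yi, yj) {
    di <- yi - xi; dj <- yj - xj
    if (abs(di) > r || abs(dj) > r) 0 else K[di + r + 1, dj + r + 1]
  }
  sideMean <- function(w) if (sum(w) > 0) sum(w * image) / sum(w) else mean(image)
  m1 <- sideMean(H); m2 <- sideMean(1 - H)
  f1 <- matrix(0, nr, nc); f2 <- matrix(0, nr, nc)
  for (xi in 1:nr) for (xj in 1:nc) {
    num1 <- den1 <- num2 <- den2 <- 0
    for (yi in 1:nr) for (yj in 1:nc) {
      k <- kAt(xi, xj, yi, yj)
      num1 <- num1 + k * H[yi, yj] * image[yi, yj]
      den1 <- den1 + k * H[yi, yj]
      num2 <- num2 + k * (1 - H[yi, yj]) * image[yi, yj]
      den2 <- den2 + k * (1 - H[yi, yj])
    }
    f1[xi, xj] <- if (den1 > 1e-12) num1 / den1 else m1
    f2[xi, xj] <- if (den2 > 1e-12) num2 / den2 else m2
  }
  E <- 0
  for (xi in 1:nr) for (xj in 1:nc)
    for (yi in 1:nr) for (yj in 1:nc) {
      k <- kAt(xi, xj, yi, yj)
      if (k == 0) next
      E <- E + params@lambda1 * k * (image[yi, yj] - f1[xi, xj])^2 * H[yi, yj] +
        params@lambda2 * k * (image[yi, yj] - f2[xi, xj])^2 * (1 - H[yi, yj])
    }
  E
}

bruteCannyEnergy <- function(phi, C, params) {
  eps <- params@epsilon
  s <- 0
  for (i in seq_len(nrow(phi))) for (j in seq_len(ncol(phi)))
    s <- s + C[i, j] * 0.5 * (1 + (2 / pi) * atan(phi[i, j] / eps))
  s
}

# Breadth-first flood fill over the 8-neighborhood from seed-strong pixels.
bruteHysteresis <- function(response, low, high) {
  nr <- nrow(response); nc <- ncol(response)
  strong <- response > high
  cand <- response >= low & response <= high
  queue <- which(strong)
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- ((p - 1) %% nr) + 1; j <- ((p - 1) %/% nr) + 1
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (cand[ii, jj] && !strong[ii, jj]) {
        strong[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * nr + ii)
      }
    }
  }
  strong
}

bruteConfusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; t <- truth[i] != 0
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Dense rotation scan: minimal axis-aligned bbox area over 0.01-degree steps,
# refined by a 100x finer pass around the coarse minimum (the minimum sits at
# an edge-aligned orientation where the area is not stationary, so the coarse
# grid alone carries O(step) relative error).
rotationScanArea <- function(points, stepDeg = 0.01) {
  areaAt <- function(aDeg) {
    a <- aDeg * pi / 180
    x <- points[, 1] * cos(a) - points[, 2] * sin(a)
    y <- points[, 1] * sin(a) + points[, 2] * cos(a)
    (max(x) - min(x)) * (max(y) - min(y))
  }
  scan <- function(angles) {
    best <- Inf; argBest <- angles[1]
    for (a in angles) {
      ar <- areaAt(a)
      if (ar < best) { best <- ar; argBest <- a }
    }
    list(area = best, angle = argBest)
  }
  coarse <- scan(seq(0, 90, by = stepDeg))
  fine <- scan(seq(coarse$angle - stepDeg, coarse$angle + stepDeg,
                   by = stepDeg / 100))
  min(coarse$area, fine$area)
}

randomPairs <- function(seed = 1) {
  set.seed(seed)
  lapply(1:4, function(i) {
    x <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
    y <- array(runif(16 * 16 * 3) > 0.6, c(16, 16, 3, 1)) * 1
    list(x = aperm(x[, , , 1], c(3, 1, 2)), y = aperm(y[, , , 1], c(3, 1, 2)))
  })
}
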