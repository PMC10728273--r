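# Level-set preprocessing: local-binary-fitting (LBF) energy combined with a
# Laplacian-of-Gaussian edge energy, explicit gradient-descent evolution,
# hysteresis edge labeling, and the crop pipeline built on them.

#' Gaussian and Laplacian-of-Gaussian kernels
#'
#' `gaussianKernel2d` is the discrete, unit-sum Gaussian used as the local
#' weighting kernel K of the LBF energy (truncated at radius `ceiling(3
#' sigma)`). `logKernel2d` is the discretized sum of second derivatives of the
#' same Gaussian, mean-corrected to sum exactly to zero so a constant image
#' yields an exactly zero response.
#'
#' @param sigma kernel width in pixels.
#' @return A square numeric matrix of side `2 * ceiling(3 * sigma) + 1`.
#' @export
gaussianKernel2d <- function(sigma) {
  k <- gaussianKernel1d(sigma)
  outer(k, k)
}

gaussianKernel1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussianKernel2d
#' @export
logKernel2d <- function(sigma) {
  r <- ceiling(3 * sigma)
  t <- seq(-r, r)
  g <- exp(-outer(t^2, t^2, `+`) / (2 * sigma^2)) / (2 * pi * sigma^2)
  rad2 <- outer(t^2, t^2, `+`)
  k <- (rad2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

# K * img with the LBF kernel, zero padding (domain-truncated, matching the
# discrete double-integral convention of the energy).
kConv <- function(img, sigma) {
  k <- gaussianKernel1d(sigma)
  .sepConv2(img, k, k)
}

#' Smoothed Heaviside step and its derivative
#'
#' `heavisideEps(z) = 1/2 (1 + (2/pi) atan(z/eps))`; `diracEps` is its
#' derivative `eps / (pi (eps^2 + z^2))`.
#'
#' @param z numeric input (any shape).
#' @param eps regularization width.
#' @return Numeric of the same shape.
#' @export
heavisideEps <- function(z, eps = 1) 0.5 * (1 + (2 / pi) * atan(z / eps))

#' @rdname heavisideEps
#' @export
diracEps <- function(z, eps = 1) eps / (pi * (eps^2 + z^2))

#' Laplacian-of-Gaussian edge response
#'
#' Convolves the image with the mean-corrected sum of second Gaussian
#' derivatives (replicated boundary), the edge field C(x, y) entering the
#' edge energy. Linear in the image; exactly zero for a constant image.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Gaussian width in pixels.
#' @return Matrix of the same shape.
#' @export
logResponse <- function(image, sigma = 3) {
  stopifnot(sigma > 0)
  .conv2Full(image, logKernel2d(sigma), TRUE)
}

# Local fit values f1 (interior) and f2 (exterior): kernel-weighted local
# intensity averages under the smoothed region memberships. Where a side has
# no local support the fit falls back to that side's global mean (or the
# image mean if the side is empty).
lbfFitValues <- function(image, Hphi, sigma) {
  KH <- kConv(Hphi, sigma)
  KHI <- kConv(Hphi * image, sigma)
  K1 <- kConv(array(1, dim(image)), sigma)
  KI <- kConv(image, sigma)
  sideMean <- function(w) if (sum(w) > 0) sum(w * image) / sum(w) else mean(image)
  m1 <- sideMean(Hphi); m2 <- sideMean(1 - Hphi)
  f1 <- ifelse(KH > 1e-12, KHI / pmax(KH, 1e-12), m1)
  f2den <- K1 - KH
  f2 <- ifelse(f2den > 1e-12, (KI - KHI) / pmax(f2den, 1e-12), m2)
  list(f1 = f1, f2 = f2, K1 = K1)
}

# Pointwise fit-error fields e1, e2: e_s(y) = sum_x K(x - y) (I(y) - f_s(x))^2,
# expanded through three kernel convolutions.
lbfErrorFields <- function(image, fit, sigma) {
  Kf1 <- kConv(fit$f1, sigma); Kf1s <- kConv(fit$f1^2, sigma)
  Kf2 <- kConv(fit$f2, sigma); Kf2s <- kConv(fit$f2^2, sigma)
  list(e1 = image^2 * fit$K1 - 2 * image * Kf1 + Kf1s,
       e2 = image^2 * fit$K1 - 2 * image * Kf2 + Kf2s)
}

#' Local-binary-fitting energy
#'
#' Discrete double integral of the kernel-weighted squared deviations of the
#' image from the local interior/exterior fit values f1, f2 under the
#' smoothed region memberships H_eps(phi), 1 - H_eps(phi). Non-negative by
#' construction.
#'
#' @param phi level-set field (matrix), interior = `phi > 0`.
#' @param image 2-D numeric matrix of matching shape.
#' @param params A [LevelSetParams-class].
#' @return Scalar energy.
#' @export
lbfEnergy <- function(phi, image, params = levelSetParams()) {
  stopifnot(identical(dim(phi), dim(image)))
  H <- heavisideEps(phi, params@epsilon)
  fit <- lbfFitValues(image, H, params@sigma)
  e <- lbfErrorFields(image, fit, params@sigma)
  sum(params@lambda1 * H * e$e1 + params@lambda2 * (1 - H) * e$e2)
}

#' Edge energy over the contour interior
#'
#' Discrete sum of the edge response field C weighted by the smoothed interior
#' membership H_eps(phi).
#'
#' @param phi level-set field.
#' @param C edge response field, e.g. from [logResponse()].
#' @param params A [LevelSetParams-class] (only `epsilon` is used).
#' @return Scalar energy.
#' @export
cannyEnergy <- function(phi, C, params = levelSetParams()) {
  stopifnot(identical(dim(phi), dim(C)))
  sum(C * heavisideEps(phi, params@epsilon))
}

#' Total level-set energy: LBF term plus edge term
#'
#' @param phi level-set field.
#' @param image 2-D image.
#' @param params A [LevelSetParams-class].
#' @param C optional precomputed edge response; defaults to
#'   `logResponse(image, params@sigma)`.
#' @return Scalar energy, exactly `lbfEnergy(...) + cannyEnergy(...)`.
#' @export
totalEnergy <- function(phi, image, params = levelSetParams(), C = NULL) {
  if (is.null(C)) C <- logResponse(image, params@sigma)
  lbfEnergy(phi, image, params) + cannyEnergy(phi, C, params)
}

# Signed distance to an axis-aligned rectangle, positive inside.
rectSignedDistance <- function(shape, inset) {
  top <- inset[1]; bottom <- shape[1] - inset[1]
  left <- inset[2]; right <- shape[2] - inset[2]
  i <- matrix(seq_len(shape[1]) - 0.5, shape[1], shape[2])
  j <- matrix(rep(seq_len(shape[2]) - 0.5, each = shape[1]), shape[1], shape[2])
  dRow <- pmin(i - top, bottom - i)
  dCol <- pmin(j - left, right - j)
  inside <- dRow > 0 & dCol > 0
  out <- -sqrt(pmin(dRow, 0)^2 + pmin(dCol, 0)^2)
  out[inside] <- pmin(dRow, dCol)[inside]
  out
}

#' Evolve the level-set field by explicit gradient descent
#'
#' Minimizes the total energy (LBF fit term plus interior-integrated edge
#' response) by explicit Euler steps `phi <- phi - tau * dE/dphi`, with the
#' local fit values refreshed every iteration. The descent direction is
#' `delta_eps(phi) * (lambda1 e1 - lambda2 e2 + C)`. Unless `phi0` is given,
#' the field starts as the signed distance to a rectangle inset 5% from the
#' border, interior positive (a large initial contour). Intensities are
#' internally rescaled to a fixed range (0..10) so the evolution speed does
#' not depend on the acquisition's intensity units; energies are reported on
#' that scale.
#'
#' Evolution stops at `maxIters` or once mean |delta phi| per pixel drops
#' below `tol`.
#'
#' @param image 2-D numeric matrix.
#' @param params A [LevelSetParams-class].
#' @param phi0 optional initial field.
#' @param trackEnergy record the total energy at the start of each iteration.
#' @param rescale rescale intensities to 0..10 internally (default TRUE).
#' @return List: `phi` (final field), `iterations`, `converged`, `energies`
#'   (numeric trace or NULL), `meanDelta` (last mean |delta phi|).
#' @export
evolveLevelSet <- function(image, params = levelSetParams(), phi0 = NULL,
                           trackEnergy = FALSE, rescale = TRUE) {
  validObject(params)
  img <- image
  if (rescale) {
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) * 10 else img * 0
  }
  C <- logResponse(img, params@sigma)
  phi <- if (is.null(phi0))
    rectSignedDistance(dim(img), pmax(round(0.05 * dim(img)), 2))
  else phi0
  energies <- if (trackEnergy) numeric(params@maxIters) else NULL
  converged <- FALSE
  meanDelta <- NA_real_
  iters <- 0L
  for (it in seq_len(params@maxIters)) {
    H <- heavisideEps(phi, params@epsilon)
    fit <- lbfFitValues(img, H, params@sigma)
    e <- lbfErrorFields(img, fit, params@sigma)
    if (trackEnergy)
      energies[it] <- sum(params@lambda1 * H * e$e1 +
                          params@lambda2 * (1 - H) * e$e2) + sum(C * H)
    force <- diracEps(phi, params@epsilon) *
      (params@lambda1 * e$e1 - params@lambda2 * e$e2 + C)
    phiNew <- phi - params@tau * force
    if (!all(is.finite(phiNew)))
      stop("level-set evolution produced non-finite phi at iteration ", it)
    meanDelta <- mean(abs(phiNew - phi))
    phi <- phiNew
    iters <- it
    if (meanDelta < params@tol) { converged <- TRUE; break }
  }
  list(phi = phi, iterations = iters, converged = converged,
       energies = if (trackEnergy) energies[seq_len(iters)] else NULL,
       meanDelta = meanDelta)
}

#' Hysteresis edge labeling
#'
#' Pixels with response above `high` are strong edges; pixels below `low` are
#' rejected; pixels in between are promoted to strong if they are 8-connected
#' (transitively) to a strong pixel.
#'
#' @param response 2-D non-negative response field (e.g. gradient or edge
#'   magnitude).
#' @param low,high thresholds, `low < high`.
#' @return An `EdgeMap`: list with logical matrix `strong`.
#' @export
hysteresisEdges <- function(response, low, high) {
  if (low >= high) stop("hysteresis thresholds must satisfy low < high")
  strong <- response > high
  cand <- response >= low & response <= high
  repeat {
    grown <- cand & neighborAny(strong)
    if (!any(grown)) break
    strong <- strong | grown
    cand <- cand & !grown
  }
  structure(list(strong = strong), class = "EdgeMap")
}

# TRUE where any 8-neighbor of m is TRUE.
neighborAny <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(h, h + di)
    ti <- max(1, 1 - di):min(h, h - di)
    sj <- max(1, 1 + dj):min(w, w + dj)
    tj <- max(1, 1 - dj):min(w, w - dj)
    out[ti, tj] <- out[ti, tj] | m[si, sj]
  }
  out
}

#' Derive the crop box of one slice
#'
#' The full edge-to-crop pipeline: evolve the level set on the slice, zero the
#' edge-response magnitude outside the converged interior (`phi <= 0`), apply
#' hysteresis with thresholds at the given percentiles of the positive
#' response magnitudes, add the converged zero-level-set contour pixels (the
#' level set's own edge estimate, which keeps the box enclosing the segmented
#' foreground even when a high-contrast lesion dominates the response
#' histogram), and return the axis-aligned, margin-expanded bounding box of
#' the minimum-area rectangle of that edge-point set. If no edge pixels
#' survive, the full-image box is returned.
#'
#' @param image 2-D slice (typically the FLAIR channel).
#' @param params A [LevelSetParams-class].
#' @param margin box margin in pixels.
#' @param lowPct,highPct hysteresis percentiles of positive |response| values.
#' @return A crop box: list with `rows`, `cols` (0-based half-open intervals).
#' @export
cropSlice <- function(image, params = levelSetParams(), margin = 2L,
                      lowPct = 70, highPct = 90) {
  ev <- evolveLevelSet(image, params)
  resp <- abs(logResponse(image, params@sigma))
  resp[ev$phi <= 0] <- 0
  pos <- resp[resp > 0]
  full <- list(rows = c(0L, nrow(image)), cols = c(0L, ncol(image)))
  interior <- ev$phi > 0
  contour <- interior & neighborAny(!interior)
  strong <- if (length(pos) >= 2L) {
    qs <- stats::quantile(pos, c(lowPct, highPct) / 100, names = FALSE)
    if (qs[1] >= qs[2]) qs[1] <- qs[2] * (1 - 1e-9)
    if (qs[1] < qs[2]) hysteresisEdges(resp, qs[1], qs[2])$strong
    else matrix(FALSE, nrow(image), ncol(image))
  } else matrix(FALSE, nrow(image), ncol(image))
  pts <- strong | contour
  if (!any(pts)) return(full)
  cropBoxFromEdges(pts, dim(image), margin)
}
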