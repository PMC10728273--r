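# Planar geometry for the crop stage: convex hull (monotone chain),
# minimum-area enclosing rectangle (edge-alignment scan over hull edges, the
# rotating-calipers optimum), and crop-box utilities.

#' Convex hull of a 2-D point set
#'
#' Monotone-chain construction; returns the hull vertices in counter-clockwise
#' order. Every vertex is one of the input points. Collinear inputs yield a
#' degenerate 2-vertex polygon; a single point yields a 1-vertex polygon.
#'
#' @param points numeric matrix with 2 columns (x, y), one row per point.
#' @return Numeric matrix of hull vertices (2 columns), counter-clockwise.
#' @export
convexHull <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("convex hull of an empty point set")
  pts <- unique(points[order(points[, 1], points[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  buildChain <- function(idx) {
    chain <- integer(0)
    for (i in idx) {
      while (length(chain) >= 2 &&
             cross(pts[chain[length(chain) - 1], ],
                   pts[chain[length(chain)], ], pts[i, ]) <= 0)
        chain <- chain[-length(chain)]
      chain <- c(chain, i)
    }
    chain
  }
  lower <- buildChain(seq_len(n))
  upper <- buildChain(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 2L) hull <- unique(c(lower, upper))
  pts[hull, , drop = FALSE]
}

#' Minimum-area enclosing rotated rectangle
#'
#' Scans rectangle orientations aligned with each hull edge; by the supporting
#' geometry of convex polygons the minimal enclosing rectangle has one side
#' collinear with a hull edge, so this scan attains the optimum. Equal-area
#' ties keep the first edge encountered in vertex order. Degenerate hulls
#' (1 or 2 vertices) yield zero-area rectangles.
#'
#' @param hull hull vertex matrix (2 columns) from [convexHull()], or any
#'   point matrix (the hull is taken first).
#' @return A `RotatedRect`: list with `center` (x, y), `size` (w, h), `angle`
#'   in degrees in [0, 90), and `area`.
#' @export
minAreaRect <- function(hull) {
  hull <- as.matrix(hull)
  if (nrow(hull) == 0L) stop("empty hull")
  if (nrow(hull) > 2L) hull <- convexHull(hull)
  mkRect <- function(center, size, angle)
    structure(list(center = center, size = size,
                   angle = angle %% 90, area = prod(size)),
              class = "RotatedRect")
  if (nrow(hull) == 1L) return(mkRect(hull[1, ], c(0, 0), 0))
  if (nrow(hull) == 2L) {
    d <- hull[2, ] - hull[1, ]
    return(mkRect((hull[1, ] + hull[2, ]) / 2, c(sqrt(sum(d^2)), 0),
                  atan2(d[2], d[1]) * 180 / pi))
  }
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    theta <- atan2(b[2] - a[2], b[1] - a[1])
    ct <- cos(-theta); st <- sin(-theta)
    rx <- hull[, 1] * ct - hull[, 2] * st
    ry <- hull[, 1] * st + hull[, 2] * ct
    w <- max(rx) - min(rx); h <- max(ry) - min(ry)
    if (is.null(best) || w * h < best$areaRaw) {
      cx <- (max(rx) + min(rx)) / 2; cy <- (max(ry) + min(ry)) / 2
      center <- c(cx * cos(theta) - cy * sin(theta),
                  cx * sin(theta) + cy * cos(theta))
      best <- list(center = center, size = c(w, h),
                   angle = theta * 180 / pi, areaRaw = w * h)
    }
  }
  mkRect(best$center, best$size, best$angle)
}

#' Corners of a rotated rectangle
#' @param rect a `RotatedRect` from [minAreaRect()].
#' @return 4 x 2 matrix of corner coordinates.
#' @export
rectCorners <- function(rect) {
  th <- rect$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  half <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) *
    rep(rect$size / 2, each = 4)
  sweep(half %*% t(R), 2, rect$center, `+`)
}

#' Axis-aligned crop box from an edge map
#'
#' Takes the strong-edge point set, computes its minimum-area rectangle, and
#' returns that rectangle's axis-aligned bounding box expanded by `margin` and
#' clipped to the image. An empty edge map yields the full-image box.
#'
#' @param edges an `EdgeMap` from [hysteresisEdges()] (or a logical matrix).
#' @param imageShape integer(2) image dimensions (rows, cols).
#' @param margin expansion in pixels.
#' @return Crop box: list with `rows` and `cols`, 0-based half-open intervals.
#' @export
cropBoxFromEdges <- function(edges, imageShape, margin = 2L) {
  strong <- if (is.list(edges)) edges$strong else edges
  if (!any(strong))
    return(list(rows = c(0L, imageShape[1]), cols = c(0L, imageShape[2])))
  idx <- which(strong, arr.ind = TRUE)  # 1-based (row, col)
  rect <- minAreaRect(cbind(idx[, 1], idx[, 2]))
  corners <- rectCorners(rect)
  r0 <- floor(min(corners[, 1])) - 1L - margin        # to 0-based, expanded
  r1 <- ceiling(max(corners[, 1])) + margin
  c0 <- floor(min(corners[, 2])) - 1L - margin
  c1 <- ceiling(max(corners[, 2])) + margin
  list(rows = c(max(0L, as.integer(r0)), min(imageShape[1], as.integer(r1))),
       cols = c(max(0L, as.integer(c0)), min(imageShape[2], as.integer(c1))))
}

# Nearest-neighbor square resize by index mapping (labels keep their values).
nearestResize <- function(m, size) {
  ri <- pmin(nrow(m), floor((seq_len(size) - 0.5) * nrow(m) / size) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(size) - 0.5) * ncol(m) / size) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Crop a slice to a box and resize to the network side length
#'
#' The crop is zero-padded to a square (bottom/right) before resizing so the
#' aspect ratio is preserved; intensities are resized bilinearly, labels by
#' nearest neighbor (preserving the label value set). A full-image box with
#' `size` equal to the (square) image side is the identity.
#'
#' @param image 2-D matrix.
#' @param box crop box from [cropBoxFromEdges()].
#' @param size output side length.
#' @param mode `"intensity"` (bilinear) or `"label"` (nearest).
#' @return `size` x `size` matrix (integer in label mode).
#' @export
applyCropResize <- function(image, box, size, mode = c("intensity", "label")) {
  mode <- match.arg(mode)
  if (size <= 0) stop("size must be positive")
  r <- box$rows; cc <- box$cols
  if (r[1] < 0 || cc[1] < 0 || r[2] > nrow(image) || cc[2] > ncol(image) ||
      r[2] <= r[1] || cc[2] <= cc[1])
    stop("crop box out of bounds or empty")
  crop <- image[(r[1] + 1):r[2], (cc[1] + 1):cc[2], drop = FALSE]
  side <- max(dim(crop))
  if (!all(dim(crop) == side)) {
    pad <- matrix(if (mode == "label") 0L else 0, side, side)
    pad[seq_len(nrow(crop)), seq_len(ncol(crop))] <- crop
    crop <- pad
  }
  if (side == size) return(crop)
  if (mode == "label") {
    out <- nearestResize(crop, size)
    storage.mode(out) <- "integer"
    out
  } else {
    EBImage::resize(crop, w = size, h = size)
  }
}
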