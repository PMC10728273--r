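# Preprocessing: z-score normalization over brain voxels, axial slicing,
# region-mask composition and 4-channel assembly.

#' Z-score normalize a volume over its brain mask
#'
#' Subtracts the mean and divides by the standard deviation computed over the
#' brain voxels only; voxels outside the mask are set to 0. For skull-stripped
#' data the natural mask is `volume != 0`.
#'
#' @param volume numeric array (any dimensionality).
#' @param brainMask logical array of the same shape; defaults to the nonzero
#'   support of `volume`.
#' @return Normalized array: masked mean 0, masked s.d. 1, zeros outside.
#' @export
zscoreNormalize <- function(volume, brainMask = volume != 0) {
  if (!any(brainMask)) stop("brain mask is empty")
  v <- volume[brainMask]
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 1e-6)
    stop("degenerate input: constant intensity over the brain mask")
  # sd() is the n-1 estimator; use the population form so masked sd is exactly 1
  n <- length(v)
  s <- s * sqrt((n - 1) / n)
  out <- array(0, dim(volume))
  out[brainMask] <- (v - mean(v)) / s
  out
}

#' Extract axial slice records from a case
#'
#' Slices are taken along the third array axis in ascending index order. With
#' `dropEmpty = TRUE` a slice is kept only if its label plane contains any
#' nonzero label (used for training data preparation; inference keeps all
#' slices).
#'
#' @param case A [MultimodalCase-class].
#' @param dropEmpty drop lesion-free slices.
#' @param targetSize side length recorded on each slice (network input size).
#' @return List of [SliceRecord-class] objects.
#' @export
axialSlices <- function(case, dropEmpty = FALSE, targetSize = 160L) {
  validObject(case)
  depth <- dim(case@seg)[3]
  records <- vector("list", depth)
  keep <- logical(depth)
  for (k in seq_len(depth)) {
    seg2d <- case@seg[, , k]
    keep[k] <- !dropEmpty || any(seg2d != 0L)
    if (!keep[k]) next
    records[[k]] <- new("SliceRecord", caseId = case@caseId,
                        sliceIndex = k - 1L,
                        images = lapply(setNames(MODALITIES, MODALITIES),
                                        function(m) slot(case, m)[, , k]),
                        seg2d = seg2d, crop = NULL,
                        targetSize = as.integer(targetSize))
  }
  records[keep]
}

#' Compose WT/TC/ET region masks from a label array
#'
#' Standard BraTS composition: whole tumor = labels \{1, 2, 4\}, tumor core =
#' \{1, 4\}, enhancing tumor = \{4\}, so the three masks are nested.
#'
#' @param seg integer array with values in \{0, 1, 2, 4\}.
#' @return List of class `RegionMasks` with logical arrays `wt`, `tc`, `et`
#'   matching the input shape.
#' @export
regionMasks <- function(seg) {
  vals <- unique(as.vector(seg))
  bad <- setdiff(vals, BRATS_LABELS)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  keepDim <- function(m) { dim(m) <- dim(seg); m }
  structure(list(wt = keepDim(seg == 1L | seg == 2L | seg == 4L),
                 tc = keepDim(seg == 1L | seg == 4L),
                 et = keepDim(seg == 4L)),
            class = "RegionMasks")
}

#' Invert region masks back to a BraTS label array
#'
#' Exact inverse of [regionMasks()]: 4 where ET, 1 where TC and not ET,
#' 2 where WT and not TC, 0 elsewhere.
#'
#' @param masks list with logical arrays `wt`, `tc`, `et`.
#' @return Integer label array.
#' @export
labelsFromMasks <- function(masks) {
  seg <- array(0L, dim(masks$wt))
  seg[masks$wt] <- 2L
  seg[masks$tc] <- 1L
  seg[masks$et] <- 4L
  seg
}

#' Stack a slice record's modalities into a 4-channel image
#'
#' Channel order is fixed: 0 FLAIR, 1 T1, 2 T1c, 3 T2 (reported here as R
#' array slices 1..4 of the first dimension).
#'
#' @param record A [SliceRecord-class], or a named list of four equally-shaped
#'   matrices.
#' @return Numeric array of shape `(4, H, W)`.
#' @export
assembleChannels <- function(record) {
  images <- if (is(record, "SliceRecord")) record@images else record
  if (!all(MODALITIES %in% names(images)))
    stop("missing modality: need ", paste(MODALITIES, collapse = ", "))
  dims <- lapply(images[MODALITIES], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("modality slices must share one shape")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  out <- array(0, c(4L, h, w))
  for (i in seq_along(MODALITIES)) out[i, , ] <- images[[MODALITIES[i]]]
  out
}

#' Preprocessing settings
#'
#' @param targetSize network input side length.
#' @param dropEmpty drop lesion-free slices (training preparation).
#' @param crop apply the level-set crop (computed on FLAIR, shared by all
#'   modalities and the labels so stacked channels stay aligned).
#' @param margin crop-box margin in pixels.
#' @param lsParams [LevelSetParams-class] for the crop.
#' @param lowPct,highPct hysteresis thresholds as percentiles of the positive
#'   edge-response magnitudes.
#' @return A plain list of settings.
#' @export
preprocessConfig <- function(targetSize = 160L, dropEmpty = TRUE, crop = TRUE,
                             margin = 2L, lsParams = levelSetParams(),
                             lowPct = 70, highPct = 90) {
  list(targetSize = as.integer(targetSize), dropEmpty = dropEmpty,
       crop = crop, margin = as.integer(margin), lsParams = lsParams,
       lowPct = lowPct, highPct = highPct)
}

#' Run the full preprocessing pipeline on one case
#'
#' Order: z-score normalize each modality over its nonzero support, slice
#' axially, derive one crop box per slice from the FLAIR channel via the
#' level-set edge pipeline, crop + zero-pad-to-square + resize everything to
#' `targetSize` (bilinear for intensities, nearest for labels), and assemble
#' the `(4, S, S)` input and `(3, S, S)` region-mask target per kept slice.
#'
#' @param case A [MultimodalCase-class].
#' @param cfg Settings from [preprocessConfig()].
#' @param outDir If non-NULL, persist each pair as `<case>_<slice>_x.npy`
#'   (float32) and `<case>_<slice>_y.npy` (uint8) plus an `index.json`.
#' @return Invisibly, a list with `pairs` (each `list(x, y, sliceIndex,
#'   caseId, crop)`) and `files` (written paths, or NULL).
#' @export
preprocessCase <- function(case, cfg = preprocessConfig(), outDir = NULL) {
  norm <- case
  for (m in MODALITIES)
    slot(norm, m) <- zscoreNormalize(slot(case, m))
  records <- axialSlices(norm, dropEmpty = cfg$dropEmpty,
                         targetSize = cfg$targetSize)
  pairs <- lapply(records, function(rec) {
    shape <- dim(rec@seg2d)
    box <- if (cfg$crop)
      cropSlice(rec@images$flair, params = cfg$lsParams, margin = cfg$margin,
                lowPct = cfg$lowPct, highPct = cfg$highPct)
    else list(rows = c(0L, shape[1]), cols = c(0L, shape[2]))
    imgs <- lapply(rec@images, applyCropResize, box = box,
                   size = cfg$targetSize, mode = "intensity")
    segR <- applyCropResize(rec@seg2d, box, cfg$targetSize, mode = "label")
    masks <- regionMasks(segR)
    y <- array(0L, c(3L, cfg$targetSize, cfg$targetSize))
    y[1, , ] <- masks$wt; y[2, , ] <- masks$tc; y[3, , ] <- masks$et
    list(x = assembleChannels(imgs), y = y, sliceIndex = rec@sliceIndex,
         caseId = rec@caseId, crop = box)
  })
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- lapply(pairs, function(p) {
      fx <- file.path(outDir, sprintf("%s_%03d_x.npy", p$caseId, p$sliceIndex))
      fy <- file.path(outDir, sprintf("%s_%03d_y.npy", p$caseId, p$sliceIndex))
      npyWrite(p$x, fx, "float32")
      npyWrite(p$y, fy, "uint8")
      list(x = fx, y = fy, sliceIndex = p$sliceIndex, caseId = p$caseId)
    })
    jsonlite::write_json(files, file.path(outDir, "index.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(pairs = pairs, files = files))
}
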