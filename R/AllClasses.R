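#' @useDynLib MRSegGAN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils write.csv head
NULL

MODALITIES <- c("flair", "t1", "t1c", "t2")
TISSUE_CLASSES <- c("background", "brain", "edema", "core", "enhancing")
BRATS_LABELS <- c(0L, 1L, 2L, 4L)

#' Configuration for the synthetic multimodal phantom generator
#'
#' Describes a BraTS-like synthetic case: a brain ellipsoid inside a
#' `volumeShape` voxel grid (1 mm isotropic) containing one or more tumors
#' built from nested ellipsoidal shells (whole tumor > tumor core > enhancing
#' tumor), with per-modality, per-tissue-class mean intensities and additive
#' Gaussian noise restricted to the brain support (the background stays
#' exactly zero, as in skull-stripped data).
#'
#' @slot volumeShape integer(3), voxels (rows, cols, slices).
#' @slot brainExtent numeric(3), fractional semi-axes of the brain ellipsoid.
#' @slot tumorCenterJitter numeric(1), voxels of uniform jitter applied to the
#'   tumor center inside the brain.
#' @slot regionRadii named numeric(3) `wt`, `tc`, `et`: radii of the nested
#'   shells as fractions of the smallest volume half-extent; strictly nested.
#' @slot contrastTable 4 x 5 numeric matrix of mean intensities, rows
#'   `flair,t1,t1c,t2`, columns `background,brain,edema,core,enhancing`.
#' @slot noiseSD numeric(1), s.d. of additive Gaussian noise (intensity units).
#' @slot nTumors integer(1), lesions per case (default 1).
#' @slot seed integer(1), default seed used when `generateCase` is not given one.
#' @export
setClass("PhantomConfig",
  representation(volumeShape = "integer", brainExtent = "numeric",
                 tumorCenterJitter = "numeric", regionRadii = "numeric",
                 contrastTable = "matrix", noiseSD = "numeric",
                 nTumors = "integer", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape <= 0L))
    msg <- c(msg, "volumeShape must be 3 positive integers")
  r <- object@regionRadii
  if (!all(c("wt", "tc", "et") %in% names(r)))
    msg <- c(msg, "regionRadii must be named wt, tc, et")
  else if (!(r["wt"] > r["tc"] && r["tc"] > r["et"] && r["et"] > 0))
    msg <- c(msg, "regionRadii must be strictly nested: wt > tc > et > 0")
  ct <- object@contrastTable
  if (!all(MODALITIES %in% rownames(ct)) || !all(TISSUE_CLASSES %in% colnames(ct)))
    msg <- c(msg, "contrastTable must cover all 4 modalities and 5 tissue classes")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@nTumors < 1L) msg <- c(msg, "nTumors must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A single multimodal case
#'
#' Four co-registered modality volumes plus the integer label volume, the
#' package's unit of I/O. Labels follow the BraTS convention: 0 background,
#' 1 tumor core (non-enhancing), 2 edema, 4 enhancing tumor.
#'
#' @slot caseId character scalar.
#' @slot flair,t1,t1c,t2 3-D numeric intensity volumes, one shape.
#' @slot seg 3-D integer label volume, values in \{0, 1, 2, 4\}.
#' @slot spacing numeric(3), mm per voxel.
#' @export
setClass("MultimodalCase",
  representation(caseId = "character", flair = "array", t1 = "array",
                 t1c = "array", t2 = "array", seg = "array",
                 spacing = "numeric"))

setValidity("MultimodalCase", function(object) {
  msg <- character()
  dims <- lapply(c(MODALITIES, "seg"), function(m) dim(slot(object, m)))
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))) ||
      length(dims[[1]]) != 3L)
    msg <- c(msg, "all five volumes must share one 3-D shape")
  if (!all(unique(as.vector(object@seg)) %in% BRATS_LABELS))
    msg <- c(msg, "seg values must be in {0, 1, 2, 4}")
  if (!any(object@flair != 0))
    msg <- c(msg, "brain support (nonzero voxels) must be nonempty")
  if (length(msg)) msg else TRUE
})

#' One axial slice across modalities
#'
#' @slot caseId character scalar.
#' @slot sliceIndex integer, 0-based index along the third volume axis.
#' @slot images named list of four 2-D matrices (`flair`, `t1`, `t1c`, `t2`).
#' @slot seg2d integer matrix with values in \{0, 1, 2, 4\}.
#' @slot crop crop box (list with `rows`, `cols`, 0-based half-open) or NULL.
#' @slot targetSize integer, network side length the slice is destined for.
#' @export
setClass("SliceRecord",
  representation(caseId = "character", sliceIndex = "integer",
                 images = "list", seg2d = "matrix", crop = "ANY",
                 targetSize = "integer"))

setValidity("SliceRecord", function(object) {
  msg <- character()
  if (!all(MODALITIES %in% names(object@images)))
    msg <- c(msg, "images must contain flair, t1, t1c, t2")
  dims <- lapply(object@images, dim)
  if (!all(vapply(dims, function(d) identical(d, dim(object@seg2d)), logical(1))))
    msg <- c(msg, "all slice images must share the seg2d shape")
  if (!all(unique(as.vector(object@seg2d)) %in% BRATS_LABELS))
    msg <- c(msg, "seg2d values must be in {0, 1, 2, 4}")
  if (object@sliceIndex < 0L) msg <- c(msg, "sliceIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Level-set energy and evolution parameters
#'
#' Constants of the combined local-binary-fitting (LBF) plus
#' Laplacian-of-Gaussian edge energy and its explicit gradient-descent
#' evolution. `lambda1`/`lambda2` weight the interior/exterior fit terms,
#' `sigma` is the Gaussian kernel width (pixels), `epsilon` the smoothed
#' Heaviside width, `tau` the evolution time step, and evolution stops after
#' `maxIters` iterations or once mean |delta phi| drops below `tol`.
#'
#' @export
setClass("LevelSetParams",
  representation(lambda1 = "numeric", lambda2 = "numeric", sigma = "numeric",
                 epsilon = "numeric", tau = "numeric", maxIters = "integer",
                 tol = "numeric"))

setValidity("LevelSetParams", function(object) {
  msg <- character()
  for (s in c("sigma", "epsilon", "tau", "tol"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Declarative description of the residual/SE segmenter
#'
#' @slot inputSize side length of the square network input; must be divisible
#'   by 16 (four pooling halvings).
#' @slot inChannels input channels (4 modalities).
#' @slot outChannels output region channels (WT, TC, ET).
#' @slot baseWidth channel width of the first encoder level; widths double per
#'   level (64 is the reference full-scale width).
#' @slot residualVariant residual-unit arrangement 1, 2 or 3 (default 3:
#'   conv-BN-ReLU, conv-BN, shortcut add, no activation after the add).
#' @slot seEnabled logical, squeeze-and-excitation attention on the encoder
#'   skip paths.
#' @slot seReduction bottleneck reduction of the SE gate.
#' @slot seed integer used for parameter initialization.
#' @export
setClass("SegmenterConfig",
  representation(inputSize = "integer", inChannels = "integer",
                 outChannels = "integer", baseWidth = "integer",
                 residualVariant = "integer", seEnabled = "logical",
                 seReduction = "integer", seed = "integer"))

setValidity("SegmenterConfig", function(object) {
  msg <- character()
  if (object@inputSize %% 16L != 0L)
    msg <- c(msg, "inputSize must be divisible by 16")
  if (object@baseWidth < 1L) msg <- c(msg, "baseWidth must be >= 1")
  if (!object@residualVariant %in% 1:3)
    msg <- c(msg, "residualVariant must be 1, 2 or 3")
  if (object@seEnabled && object@baseWidth < object@seReduction)
    msg <- c(msg, "seReduction must not exceed the smallest channel width")
  if (length(msg)) msg else TRUE
})

#' Declarative description of the multiscale feature critic
#'
#' A plain convolutional network of stride-2 blocks whose per-scale feature
#' maps feed the multiscale L1 loss; the number of scales L equals
#' `length(widths)`.
#'
#' @export
setClass("CriticConfig",
  representation(inChannels = "integer", widths = "integer",
                 leakySlope = "numeric", seed = "integer"))

setValidity("CriticConfig", function(object) {
  if (length(object@widths) < 1L || any(object@widths <= 0L))
    return("widths must be positive")
  TRUE
})

#' Adversarial training configuration
#'
#' @slot epochs training epochs (reference setting: 150).
#' @slot learningRate Adam step size for both networks (reference: 2e-4).
#' @slot batchSize slices per batch.
#' @slot splitRatio training fraction of the case-level split (reference: 0.8).
#' @slot alternation critic steps per segmenter step.
#' @slot seed master seed covering shuffling and initialization.
#' @slot checkpointDir,logPath output locations ("" to disable).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 batchSize = "integer", splitRatio = "numeric",
                 alternation = "integer", seed = "integer",
                 checkpointDir = "character", logPath = "character"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@splitRatio <= 0 || object@splitRatio >= 1)
    msg <- c(msg, "splitRatio must be in (0, 1)")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", paste(object@volumeShape, collapse = " x "),
      "voxels;", object@nTumors, "tumor(s); region radii",
      paste(sprintf("%s=%.3f", names(object@regionRadii), object@regionRadii),
            collapse = ", "),
      sprintf("; noise sd %.2f\n", object@noiseSD))
})

setMethod("show", "MultimodalCase", function(object) {
  d <- dim(object@seg)
  cat("MultimodalCase", object@caseId, ":", paste(d, collapse = " x "),
      "voxels, labels {", paste(sort(unique(as.vector(object@seg))),
                                collapse = ", "), "}\n")
})

setMethod("show", "SliceRecord", function(object) {
  cat("SliceRecord", object@caseId, "slice", object@sliceIndex, ":",
      paste(dim(object@seg2d), collapse = " x "),
      if (any(object@seg2d != 0L)) "(lesion)" else "(no lesion)", "\n")
})

setMethod("show", "SegmenterConfig", function(object) {
  cat(sprintf("SegmenterConfig: %d x %d x %d -> %d channels, base width %d, residual variant %d, SE %s\n",
              object@inputSize, object@inputSize, object@inChannels,
              object@outChannels, object@baseWidth, object@residualVariant,
              if (object@seEnabled) sprintf("on (r=%d)", object@seReduction) else "off"))
})

setMethod("show", "LevelSetParams", function(object) {
  cat(sprintf("LevelSetParams: lambda=(%.2g, %.2g), sigma=%.2g, epsilon=%.2g, tau=%.2g, maxIters=%d, tol=%.2g\n",
              object@lambda1, object@lambda2, object@sigma, object@epsilon,
              object@tau, object@maxIters, object@tol))
})

# ---- constructors -----------------------------------------------------------

#' Default modality-by-tissue mean intensity table
#'
#' Arbitrary-unit class means loosely mimicking the contrast ordering of the
#' four MRI modalities (e.g. edema bright on FLAIR/T2, enhancing tumor bright
#' on T1c); background is exactly zero.
#' @return 4 x 5 numeric matrix.
#' @export
defaultContrastTable <- function() {
  m <- rbind(
    flair = c(background = 0, brain =  90, edema = 200, core = 160, enhancing = 150),
    t1    = c(background = 0, brain = 120, edema =  90, core =  70, enhancing = 110),
    t1c   = c(background = 0, brain = 120, edema =  90, core =  80, enhancing = 220),
    t2    = c(background = 0, brain = 100, edema = 180, core = 200, enhancing = 140))
  m
}

#' Create a phantom generator configuration
#'
#' @param volumeShape integer(3) voxel grid, default the BraTS 240 x 240 x 155.
#' @param brainExtent fractional semi-axes of the brain ellipsoid.
#' @param tumorCenterJitter uniform jitter (voxels) of the tumor center.
#' @param regionRadii named fractions `wt`, `tc`, `et` of the smallest volume
#'   half-extent; must be strictly nested.
#' @param contrastTable per-modality, per-class mean intensities.
#' @param noiseSD additive Gaussian noise s.d. inside the brain support.
#' @param nTumors lesions per case.
#' @param seed default seed.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(volumeShape = c(240L, 240L, 155L),
                          brainExtent = c(0.8, 0.9, 0.8),
                          tumorCenterJitter = 10,
                          regionRadii = c(wt = 0.45, tc = 0.28, et = 0.15),
                          contrastTable = defaultContrastTable(),
                          noiseSD = 5, nTumors = 1L, seed = 1L) {
  new("PhantomConfig", volumeShape = as.integer(volumeShape),
      brainExtent = brainExtent, tumorCenterJitter = tumorCenterJitter,
      regionRadii = regionRadii, contrastTable = contrastTable,
      noiseSD = noiseSD, nTumors = as.integer(nTumors),
      seed = as.integer(seed))
}

#' Create level-set parameters
#' @param lambda1,lambda2 interior/exterior fit weights (both 1).
#' @param sigma Gaussian kernel width, pixels.
#' @param epsilon smoothed Heaviside width.
#' @param tau evolution time step.
#' @param maxIters iteration cap.
#' @param tol convergence threshold on mean |delta phi|.
#' @return A [LevelSetParams-class] object.
#' @export
levelSetParams <- function(lambda1 = 1, lambda2 = 1, sigma = 3, epsilon = 1,
                           tau = 0.1, maxIters = 200L, tol = 1e-3) {
  new("LevelSetParams", lambda1 = lambda1, lambda2 = lambda2, sigma = sigma,
      epsilon = epsilon, tau = tau, maxIters = as.integer(maxIters), tol = tol)
}

#' Create a segmenter configuration
#' @param inputSize square input side, divisible by 16.
#' @param inChannels,outChannels input modalities and output regions.
#' @param baseWidth first-level channel width (64 at full scale).
#' @param residualVariant residual unit arrangement, 1|2|3.
#' @param seEnabled,seReduction squeeze-and-excitation gate settings.
#' @param seed initialization seed.
#' @return A [SegmenterConfig-class] object.
#' @export
segmenterConfig <- function(inputSize = 160L, inChannels = 4L,
                            outChannels = 3L, baseWidth = 64L,
                            residualVariant = 3L, seEnabled = TRUE,
                            seReduction = 16L, seed = 1L) {
  new("SegmenterConfig", inputSize = as.integer(inputSize),
      inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
      baseWidth = as.integer(baseWidth),
      residualVariant = as.integer(residualVariant), seEnabled = seEnabled,
      seReduction = as.integer(seReduction), seed = as.integer(seed))
}

#' Create a critic configuration
#' @param inChannels critic input channels (12: 3 regions x 4 modalities).
#' @param widths channel widths of the stride-2 blocks; length gives the
#'   number of scales L.
#' @param leakySlope negative slope of the leaky ReLU.
#' @param seed initialization seed.
#' @return A [CriticConfig-class] object.
#' @export
criticConfig <- function(inChannels = 12L, widths = c(64L, 128L, 256L, 512L),
                         leakySlope = 0.2, seed = 1L) {
  new("CriticConfig", inChannels = as.integer(inChannels),
      widths = as.integer(widths), leakySlope = leakySlope,
      seed = as.integer(seed))
}

#' Create a training configuration
#' @param epochs,learningRate,batchSize,splitRatio,alternation,seed see slots.
#' @param checkpointDir,logPath output locations; "" disables.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 150L, learningRate = 2e-4, batchSize = 16L,
                        splitRatio = 0.8, alternation = 1L, seed = 1L,
                        checkpointDir = "", logPath = "") {
  new("TrainConfig", epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), splitRatio = splitRatio,
      alternation = as.integer(alternation), seed = as.integer(seed),
      checkpointDir = checkpointDir, logPath = logPath)
}

# Run code with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
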