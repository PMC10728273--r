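# Synthetic multimodal phantom generation: nested ellipsoidal tumor shells
# inside a brain ellipsoid, class-mean intensities plus Gaussian noise.

# Squared normalized distance of every voxel to an ellipsoid center.
ellipsoidField <- function(shape, center, semiAxes) {
  gx <- (seq_len(shape[1]) - center[1]) / semiAxes[1]
  gy <- (seq_len(shape[2]) - center[2]) / semiAxes[2]
  gz <- (seq_len(shape[3]) - center[3]) / semiAxes[3]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

#' Generate one synthetic multimodal case
#'
#' Builds a brain ellipsoid, places `nTumors` nested ellipsoidal lesions
#' (enhancing core inside tumor core inside whole tumor) at jittered centers
#' inside it, assigns per-modality class-mean intensities from the contrast
#' table and adds Gaussian noise restricted to the brain support, so the
#' background stays exactly zero as in skull-stripped acquisitions. Fully
#' deterministic given `(cfg, seed)`.
#'
#' @param cfg A [PhantomConfig-class].
#' @param seed Integer seed; defaults to the seed stored in `cfg`.
#' @return A [MultimodalCase-class].
#' @examples
#' cfg <- phantomConfig(volumeShape = c(48L, 48L, 32L))
#' case <- generateCase(cfg, seed = 7)
#' table(segVolume(case))
#' @export
generateCase <- function(cfg, seed = cfg@seed) {
  validObject(cfg)
  shape <- cfg@volumeShape
  withSeed(seed, {
    half <- shape / 2
    brainAxes <- half * cfg@brainExtent
    brain <- ellipsoidField(shape, half, brainAxes) <= 1
    rmax <- min(half)
    seg <- array(0L, shape)
    for (t in seq_len(cfg@nTumors)) {
      # random center, kept deep enough inside the brain for the WT shell
      repeat {
        u <- stats::runif(3, -1, 1) * cfg@tumorCenterJitter
        center <- half + u
        margin <- cfg@regionRadii["wt"] * rmax
        d <- sum(((center - half) / pmax(brainAxes - margin, 1))^2)
        if (d <= 1) break
      }
      for (reg in c("wt", "tc", "et")) {
        ax <- rep(cfg@regionRadii[reg] * rmax, 3)
        mask <- ellipsoidField(shape, center, ax) <= 1
        lab <- c(wt = 2L, tc = 1L, et = 4L)[reg]
        seg[mask] <- lab
      }
    }
    seg[!brain] <- 0L
    vols <- lapply(MODALITIES, function(m) {
      v <- array(0, shape)
      means <- cfg@contrastTable[m, ]
      v[brain] <- means[["brain"]]
      v[seg == 2L] <- means[["edema"]]
      v[seg == 1L] <- means[["core"]]
      v[seg == 4L] <- means[["enhancing"]]
      if (cfg@noiseSD > 0) {
        nb <- sum(brain)
        v[brain] <- v[brain] + stats::rnorm(nb, 0, cfg@noiseSD)
      }
      v
    })
    names(vols) <- MODALITIES
    new("MultimodalCase", caseId = sprintf("phantom_seed%d", as.integer(seed)),
        flair = vols$flair, t1 = vols$t1, t1c = vols$t1c, t2 = vols$t2,
        seg = seg, spacing = c(1, 1, 1))
  })
}

#' @describeIn generateCase Case identifier accessor.
#' @param case A [MultimodalCase-class].
#' @export
caseId <- function(case) case@caseId

#' @describeIn generateCase Modality volume accessor.
#' @param modality One of `"flair"`, `"t1"`, `"t1c"`, `"t2"`.
#' @export
modalityVolume <- function(case, modality = MODALITIES) {
  modality <- match.arg(modality)
  slot(case, modality)
}

#' @describeIn generateCase Label volume accessor.
#' @export
segVolume <- function(case) case@seg

#' Write cases to a BraTS-style NIfTI directory tree
#'
#' One sub-directory per case holding `<case>_flair.nii.gz`, `<case>_t1.nii.gz`,
#' `<case>_t1ce.nii.gz`, `<case>_t2.nii.gz` and `<case>_seg.nii.gz`, plus a
#' JSON manifest listing every file written.
#'
#' @param cases list of [MultimodalCase-class] objects.
#' @param outDir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest, invisibly: a list with one entry per case mapping
#'   volume names to file paths.
#' @export
writeDataset <- function(cases, outDir, overwrite = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fileSuffix <- c(flair = "flair", t1 = "t1", t1c = "t1ce", t2 = "t2")
  manifest <- lapply(cases, function(case) {
    cdir <- file.path(outDir, case@caseId)
    dir.create(cdir, showWarnings = FALSE)
    files <- list()
    for (m in MODALITIES) {
      p <- file.path(cdir, sprintf("%s_%s.nii.gz", case@caseId, fileSuffix[[m]]))
      RNifti::writeNifti(RNifti::asNifti(slot(case, m)), p)
      files[[m]] <- p
    }
    p <- file.path(cdir, sprintf("%s_seg.nii.gz", case@caseId))
    RNifti::writeNifti(RNifti::asNifti(case@seg, datatype = "int16"), p)
    files[["seg"]] <- p
    files
  })
  names(manifest) <- vapply(cases, caseId, character(1))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read one case back from a BraTS-style directory
#'
#' Accepts either a case directory created by [writeDataset()] or any
#' directory with the five standard `<case>_{flair,t1,t1ce,t2,seg}.nii.gz`
#' volumes.
#'
#' @param caseDir directory holding the five NIfTI volumes.
#' @return A [MultimodalCase-class].
#' @export
readCase <- function(caseDir) {
  id <- basename(normalizePath(caseDir, mustWork = TRUE))
  readVol <- function(suffix) {
    p <- list.files(caseDir, pattern = paste0("_", suffix, "\\.nii(\\.gz)?$"),
                    full.names = TRUE)
    if (length(p) != 1L)
      stop("expected exactly one *_", suffix, ".nii.gz in ", caseDir)
    v <- RNifti::readNifti(p[1])
    array(as.vector(v), dim(v))
  }
  seg <- readVol("seg")
  storage.mode(seg) <- "integer"
  new("MultimodalCase", caseId = id, flair = readVol("flair"),
      t1 = readVol("t1"), t1c = readVol("t1ce"), t2 = readVol("t2"),
      seg = seg, spacing = c(1, 1, 1))
}
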