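# Evaluation metrics and adversarial objective: confusion counts, Dice,
# the masked region-by-modality critic input, the multiscale L1 feature loss,
# and the paired t-test utility.

#' Per-pixel confusion counts of two binary masks
#'
#' @param pred,truth binary (logical or 0/1) arrays of equal shape.
#' @return A `ConfusionCounts` list: `tp`, `tn`, `fp`, `fn` (their sum is the
#'   pixel count).
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical shapes")
  p <- as.logical(pred); t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) stop("masks must be binary")
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "ConfusionCounts")
}

#' Dice similarity coefficient
#'
#' `2 TP / (FP + 2 TP + FN)`; 1.0 indicates perfect segmentation. When both
#' masks are empty (a slice with no tumor) the score is defined as 1.0; when
#' exactly one is empty the formula already gives 0.0.
#'
#' @param counts a `ConfusionCounts` from [confusionCounts()].
#' @return Score in [0, 1].
#' @export
dice <- function(counts) {
  den <- counts$fp + 2 * counts$tp + counts$fn
  if (den == 0) return(1.0)
  2 * counts$tp / den
}

#' @describeIn dice Dice of two binary masks directly.
#' @param pred,truth binary arrays of equal shape.
#' @export
diceFromMasks <- function(pred, truth) dice(confusionCounts(pred, truth))

#' Region-by-modality masked critic input
#'
#' Multiplies each of the 3 region mask channels by each of the 4 modality
#' channels and stacks the 12 products region-major (region r, modality m at
#' channel `(r - 1) * 4 + m`). This is how a 3-channel mask and a 4-channel
#' image are reconciled into one critic input.
#'
#' @param image array `(4, H, W)`.
#' @param mask array `(3, H, W)` of region probabilities or binaries.
#' @return Array `(12, H, W)`.
#' @export
maskedPair <- function(image, mask) {
  di <- dim(image); dm <- dim(mask)
  if (length(di) != 3L || length(dm) != 3L || !all(di[2:3] == dm[2:3]))
    stop("image and mask must be (4, H, W) and (3, H, W) with matching H, W")
  out <- array(0, c(di[1] * dm[1], di[2], di[3]))
  for (r in seq_len(dm[1]))
    for (m in seq_len(di[1]))
      out[(r - 1) * di[1] + m, , ] <- mask[r, , ] * image[m, , ]
  out
}

# Batched (H, W, C, N) variant used by the training loop, plus its gradient
# with respect to the mask channels.
maskedPairHWCN <- function(image, mask) {
  di <- dim(image); dm <- dim(mask)
  out <- array(0, c(di[1], di[2], di[3] * dm[3], di[4]))
  for (r in seq_len(dm[3]))
    for (m in seq_len(di[3]))
      out[, , (r - 1) * di[3] + m, ] <- mask[, , r, ] * image[, , m, ]
  out
}

maskedPairBwdMask <- function(image, dout) {
  di <- dim(image)
  nr <- dim(dout)[3] / di[3]
  dmask <- array(0, c(di[1], di[2], nr, di[4]))
  for (r in seq_len(nr)) {
    acc <- 0
    for (m in seq_len(di[3]))
      acc <- acc + image[, , m, ] * dout[, , (r - 1) * di[3] + m, ]
    dmask[, , r, ] <- acc
  }
  dmask
}

#' Multiscale L1 feature loss
#'
#' `(1 / L) * sum_i mean(|f_i^a - f_i^b|)`: the mean absolute difference
#' between two feature hierarchies, averaged over the L scales, with the
#' per-scale L1 taken as the elementwise mean so every scale contributes
#' comparably. Symmetric, non-negative, zero iff the hierarchies are
#' identical.
#'
#' @param featuresA,featuresB lists of L equally-shaped arrays.
#' @return List: `loss` (scalar) and `perScale` (length-L breakdown).
#' @export
multiscaleL1 <- function(featuresA, featuresB) {
  if (length(featuresA) != length(featuresB))
    stop("feature lists must have equal length")
  perScale <- mapply(function(a, b) {
    if (!identical(dim(a), dim(b))) stop("feature shapes must match per scale")
    mean(abs(a - b))
  }, featuresA, featuresB)
  list(loss = mean(perScale), perScale = as.numeric(perScale))
}

# d(loss)/d(featuresA): sign(a - b) / (L * numel_i)
multiscaleL1GradA <- function(featuresA, featuresB) {
  L <- length(featuresA)
  mapply(function(a, b) sign(a - b) / (L * length(a)),
         featuresA, featuresB, SIMPLIFY = FALSE)
}

#' Paired t-test on matched score lists
#'
#' Classical paired t-test on the differences, two-sided p from the t
#' distribution with n - 1 degrees of freedom.
#'
#' @param scoresA,scoresB numeric vectors of equal length >= 2.
#' @return List: `statistic` (t), `p.value`, `df`.
#' @export
pairedTTest <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB) || length(scoresA) < 2L)
    stop("need two equal-length score vectors with n >= 2")
  d <- scoresA - scoresB
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1))
    stop("degenerate input: zero variance of paired differences")
  tt <- stats::t.test(scoresA, scoresB, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}
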