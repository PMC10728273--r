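# MRSegGAN

Adversarial multimodal brain tumor segmentation in R, end to end: a seeded
synthetic BraTS-style phantom generator, level-set-based preprocessing and
cropping, a residual U-Net segmenter with squeeze-and-excitation attention, a
multiscale feature critic trained against it with an L1 feature loss, and
Dice-based evaluation of the nested whole-tumor / tumor-core / enhancing-tumor
regions. The package is aimed at researchers who want a fully inspectable,
dependency-light reference implementation of this family of adversarial
segmentation methods: every layer's forward and backward pass is implemented
in the package itself (R + C++ kernels), so the complete pipeline runs on a
plain CPU with no deep-learning runtime.

## The method in brief

**Segmenter.** A nine-unit-level residual U-Net on 160x160 four-channel
(FLAIR, T1, T1c, T2) axial slices: four encoder levels (widths 64-512, 2x2
max-pool between levels), a 1024-channel bridge at 10x10, four decoder levels
fed by parameter-free 2x upsampling concatenated with SE-gated encoder skips
(decoder input widths 1536/768/384/192), and a 1x1 sigmoid head producing
three nested region probabilities — 19 main-path convolutions in total.

**Objective.** With segmenter S and critic C, training solves

```
min_S max_C  (1/L) * sum_i || f_C^i(x o S(x)) - f_C^i(x o y) ||_1
```

where `f_C^i` is the critic's i-th scale feature map and `x o m` is the
masked input: all 12 region-by-modality products of the image with the mask.
Both networks use Adam (betas 0.5/0.999, learning rate 2e-4), alternating one
critic ascent and one segmenter descent step per batch.

**Preprocessing.** Per modality z-scoring over the brain support; axial
slicing (lesion-free slices optionally dropped for training); a per-slice
crop box derived from a level-set evolution that minimizes a local-binary-
fitting energy plus a Laplacian-of-Gaussian edge energy, followed by
hysteresis edge labeling, convex hull and minimum-area enclosing rectangle;
crops are padded to square and resized to the network input size.

**Evaluation.** Dice = 2TP / (FP + 2TP + FN) per region (1.0 when both masks
are empty), reported per case with region means and their average, plus a
paired t-test utility for method comparisons.

## Worked example

Generate two tiny phantom cases, train briefly at desk scale, and evaluate:

```r
library(MRSegGAN)

pcfg <- phantomConfig(volumeShape = c(64L, 64L, 48L))
prep <- preprocessConfig(targetSize = 64L, dropEmpty = TRUE)
pairsOf <- function(seeds) do.call(c, lapply(seeds, function(s)
  preprocessCase(generateCase(pcfg, seed = s), prep)$pairs))

res <- trainModel(
  trainConfig(epochs = 20L, batchSize = 16L, seed = 7L),
  trainPairs = pairsOf(101:110)[1:200],
  valPairs   = pairsOf(111:112),
  segCfg     = segmenterConfig(inputSize = 64L, baseWidth = 8L, seReduction = 4L, seed = 7L),
  criticCfg  = criticConfig(widths = c(16L, 32L, 64L, 128L), seed = 8L))
```

Each epoch logs a structured line; on this configuration the run ends with

```
epoch=20 lossS=0.102342 lossC=0.100048 valWT=0.8267 valTC=0.4397 valET=0.2117 seed=7
```

i.e. the adversarial feature loss has fallen from 0.21 to 0.10 and validation
whole-tumor Dice has risen from 0.14 (untrained) to 0.83; the smaller core
and enhancing regions learn more slowly at this scale. Full volumes are then
segmented and scored with

```r
case <- generateCase(pcfg, seed = 200)
pred <- segmentCase(res$segmenter, case, prep)
evaluateSegmentations(list(pred), list(segVolume(case)))
```

which reports per-case WT/TC/ET Dice, the three region means and their grand
average — the layout used for method comparison tables.

A thin command-line front end over the same functions is installed at
`inst/cli/mrseggan.R` (subcommands `phantom`, `preprocess`, `crop`, `train`,
`segment`, `evaluate`).

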