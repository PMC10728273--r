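# The residual/SE segmenter and the multiscale feature critic.
#
# The segmenter is a 9-unit-level residual U-Net: 4 encoder levels, a bridge,
# and 4 decoder levels, each a residual unit of two 3x3 convolutions; a 2x2
# max-pool follows each encoder level, a parameter-free 2x upsample plus skip
# concatenation precedes each decoder level, and a final 1x1 convolution with
# a per-channel sigmoid produces the 3 region probabilities (WT, TC, ET).
# With base width 64 that gives 19 main-path convolutions and the channel
# ladder 64/128/256/512 down, 1024 at the bridge, and concatenated decoder
# inputs 1536/768/384/192. Squeeze-and-excitation gates sit after each encoder
# unit; the skip tensor is taken after the gate, before pooling.

#' Describe one residual unit
#'
#' Returns the declarative layer list of a residual unit of the requested
#' variant. Variant 1 is fully pre-activated ((BN, ReLU, conv) twice);
#' variants 2 and 3 are (conv, BN, ReLU) then (conv, BN) plus the shortcut
#' add, with variant 2 applying a ReLU after the add and variant 3 not. The
#' shortcut is the identity when channel counts match and a 1x1 projection
#' otherwise.
#'
#' @param variant 1, 2 or 3.
#' @param inChannels,outChannels channel counts.
#' @return A `BlockSpec`: list with `variant`, `inChannels`, `outChannels`,
#'   `layers` (character vector in order) and `shortcut`.
#' @export
buildResidualUnit <- function(variant, inChannels, outChannels) {
  if (!variant %in% 1:3) stop("unknown residual variant: ", variant)
  layers <- switch(variant,
    `1` = c("bn", "relu", "conv3x3", "bn", "relu", "conv3x3", "add"),
    `2` = c("conv3x3", "bn", "relu", "conv3x3", "bn", "add", "relu"),
    `3` = c("conv3x3", "bn", "relu", "conv3x3", "bn", "add"))
  structure(list(variant = as.integer(variant),
                 inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 layers = layers,
                 shortcut = if (inChannels == outChannels) "identity"
                            else "projection1x1"),
            class = "BlockSpec")
}

#' Describe a squeeze-and-excitation unit
#'
#' Global average pool, a two-layer bottleneck (`channels / reduction`), a
#' sigmoid gate, and channelwise rescaling; output shape equals input shape.
#'
#' @param channels input channel count.
#' @param reduction bottleneck reduction factor; must not exceed `channels`.
#' @return A `BlockSpec` describing the gate.
#' @export
buildSEUnit <- function(channels, reduction = 16L) {
  if (reduction > channels)
    stop("SE reduction (", reduction, ") exceeds channel count (", channels, ")")
  structure(list(channels = as.integer(channels),
                 bottleneck = as.integer(max(1L, channels %/% reduction)),
                 layers = c("global_avg_pool", "fc", "relu", "fc", "sigmoid",
                            "scale")),
            class = "BlockSpec")
}

#' Build the segmenter
#'
#' Constructs all parameters (deterministically from `cfg@seed`) of the
#' 9-level residual U-Net with SE-gated skips described above.
#'
#' @param cfg A [SegmenterConfig-class].
#' @return A model list with `cfg`, `params`, `run` (batch-norm running
#'   statistics) and `arch` (census metadata).
#' @export
buildSegmenter <- function(cfg = segmenterConfig()) {
  validObject(cfg)
  bw <- cfg@baseWidth
  encIn <- c(cfg@inChannels, bw, 2L * bw, 4L * bw)
  encOut <- c(bw, 2L * bw, 4L * bw, 8L * bw)
  decIn <- c(3L * bw, 6L * bw, 12L * bw, 24L * bw)   # upsampled + skip
  decOut <- c(bw, 2L * bw, 4L * bw, 8L * bw)
  withSeed(cfg@seed, {
    params <- list()
    run <- list()
    for (k in 1:4) {
      nm <- paste0("enc", k)
      params[[nm]] <- makeUnitParams(encIn[k], encOut[k], cfg@residualVariant)
      run[[nm]] <- list(bn1 = newBnRun(if (cfg@residualVariant == 1L) encIn[k] else encOut[k]),
                        bn2 = newBnRun(encOut[k]))
      if (cfg@seEnabled) {
        cmid <- max(1L, encOut[k] %/% cfg@seReduction)
        params[[paste0("se", k)]] <- list(
          fc1 = list(w = heInit(c(cmid, encOut[k]), encOut[k]), b = numeric(cmid)),
          fc2 = list(w = heInit(c(encOut[k], cmid), cmid), b = numeric(encOut[k])))
      }
    }
    params$bridge <- makeUnitParams(8L * bw, 16L * bw, cfg@residualVariant)
    run$bridge <- list(bn1 = newBnRun(if (cfg@residualVariant == 1L) 8L * bw else 16L * bw),
                       bn2 = newBnRun(16L * bw))
    for (k in 4:1) {
      nm <- paste0("dec", k)
      params[[nm]] <- makeUnitParams(decIn[k], decOut[k], cfg@residualVariant)
      run[[nm]] <- list(bn1 = newBnRun(if (cfg@residualVariant == 1L) decIn[k] else decOut[k]),
                        bn2 = newBnRun(decOut[k]))
    }
    params$head <- makeConvParams(1L, bw, cfg@outChannels)
    mainConvs <- c(t(outer(c(paste0("enc", 1:4), "bridge", paste0("dec", 4:1)),
                           c("conv1", "conv2"), paste, sep = ".")), "head")
    list(kind = "segmenter", cfg = cfg, params = params, run = run,
         arch = list(mainConvs = mainConvs, levels = 9L,
                     encWidths = encOut, bridgeWidth = 16L * bw))
  })
}

#' Segmenter forward pass
#'
#' @param model from [buildSegmenter()].
#' @param x input array `(H, W, 4, N)` (or `(4, H, W)` for a single
#'   channels-first slice, which is transposed automatically).
#' @param train batch statistics (TRUE) or running statistics (FALSE) in the
#'   batch-norm layers; TRUE also updates the running statistics.
#' @param withCache keep every intermediate needed for a backward pass.
#' @return List: `out` (probabilities, `(H, W, 3, N)`), `bridge` (bridge
#'   feature map), `cache` (or NULL), `run` (updated running stats).
#' @export
forwardSegmenter <- function(model, x, train = FALSE, withCache = FALSE) {
  cfg <- model$cfg
  if (length(dim(x)) == 3L && dim(x)[1] == cfg@inChannels)
    x <- array(aperm(x, c(2, 3, 1)), c(dim(x)[2], dim(x)[3], dim(x)[1], 1))
  p <- model$params; run <- model$run
  variant <- cfg@residualVariant
  caches <- if (withCache) list() else NULL
  skips <- list()
  cur <- x
  for (k in 1:4) {
    nm <- paste0("enc", k)
    u <- unitFwd(cur, p[[nm]], run[[nm]], variant, train)
    run[[nm]] <- u$run
    if (withCache) caches[[nm]] <- u$cache
    s <- u$y
    if (cfg@seEnabled) {
      se <- p[[paste0("se", k)]]
      sf <- seFwd(s, se$fc1$w, se$fc1$b, se$fc2$w, se$fc2$b)
      s <- sf$y
      if (withCache) caches[[paste0("se", k)]] <- sf$cache
    }
    skips[[k]] <- s
    mp <- .maxpool2Fwd(s)
    if (withCache) caches[[paste0("pool", k)]] <- list(idx = mp$idx, dim = dim(s))
    cur <- mp$y
  }
  u <- unitFwd(cur, p$bridge, run$bridge, variant, train)
  run$bridge <- u$run
  if (withCache) caches$bridge <- u$cache
  bridge <- u$y
  cur <- bridge
  for (k in 4:1) {
    nm <- paste0("dec", k)
    up <- .upsample2Fwd(cur)
    cat_ <- ccat(up, skips[[k]])
    if (withCache) caches[[paste0("cat", k)]] <- dim(up)[3]
    u <- unitFwd(cat_, p[[nm]], run[[nm]], variant, train)
    run[[nm]] <- u$run
    if (withCache) caches[[nm]] <- u$cache
    cur <- u$y
  }
  logits <- .conv2dFwd(cur, p$head$w, p$head$b, 1L, 0L)
  out <- sigmoidFwd(logits)
  if (withCache) { caches$headIn <- cur; caches$out <- out }
  list(out = out, bridge = bridge, cache = caches, run = run)
}

# Backward through the segmenter given d(loss)/d(probabilities).
backwardSegmenter <- function(model, cache, dout) {
  p <- model$params
  cfg <- model$cfg
  grads <- list()
  dlogits <- sigmoidBwdFromY(cache$out, dout)
  hb <- .conv2dBwd(cache$headIn, p$head$w, dlogits, 1L, 0L, TRUE)
  grads$head <- list(w = hb$dw, b = hb$db)
  dcur <- hb$dx
  dskips <- vector("list", 4)
  for (k in 1:4) {
    nm <- paste0("dec", k)
    ub <- unitBwd(cache[[nm]], dcur, p[[nm]])
    grads[[nm]] <- ub$grads
    sp <- csplit(ub$dx, cache[[paste0("cat", k)]])
    dskips[[k]] <- sp$b
    dcur <- .upsample2Bwd(sp$a)
  }
  ub <- unitBwd(cache$bridge, dcur, p$bridge)
  grads$bridge <- ub$grads
  dcur <- ub$dx
  for (k in 4:1) {
    pl <- cache[[paste0("pool", k)]]
    ds <- .maxpool2Bwd(dcur, pl$idx, pl$dim[1], pl$dim[2]) + dskips[[k]]
    if (cfg@seEnabled) {
      se <- p[[paste0("se", k)]]
      sb <- seBwd(cache[[paste0("se", k)]], ds, se$fc1$w, se$fc2$w)
      grads[[paste0("se", k)]] <- list(fc1 = list(w = sb$dw1, b = sb$db1),
                                       fc2 = list(w = sb$dw2, b = sb$db2))
      ds <- sb$dx
    }
    nm <- paste0("enc", k)
    ub <- unitBwd(cache[[nm]], ds, p[[nm]])
    grads[[nm]] <- ub$grads
    dcur <- ub$dx
  }
  list(grads = grads, dx = dcur)
}

#' Build the critic
#'
#' A plain convolutional network of stride-2 (conv 3x3, BN, leaky-ReLU)
#' blocks; its forward pass returns the feature map of every block, the
#' hierarchy the multiscale L1 loss compares.
#'
#' @param cfg A [CriticConfig-class].
#' @return A model list with `cfg`, `params`, `run` and `arch`.
#' @export
buildCritic <- function(cfg = criticConfig()) {
  validObject(cfg)
  withSeed(cfg@seed, {
    params <- list(); run <- list()
    cin <- cfg@inChannels
    for (i in seq_along(cfg@widths)) {
      nm <- paste0("block", i)
      params[[nm]] <- list(conv = makeConvParams(3L, cin, cfg@widths[i]),
                           bn = list(g = rep(1, cfg@widths[i]),
                                     b = numeric(cfg@widths[i])))
      run[[nm]] <- newBnRun(cfg@widths[i])
      cin <- cfg@widths[i]
    }
    list(kind = "critic", cfg = cfg, params = params, run = run,
         arch = list(mainConvs = paste0("block", seq_along(cfg@widths), ".conv"),
                     levels = length(cfg@widths)))
  })
}

#' Critic forward pass
#'
#' @param model from [buildCritic()].
#' @param x input array `(H, W, C, N)`.
#' @param train,withCache as in [forwardSegmenter()].
#' @return List: `features` (list of L per-scale feature maps, halving in
#'   spatial size), `cache`, `run`.
#' @export
forwardCritic <- function(model, x, train = FALSE, withCache = FALSE) {
  p <- model$params; run <- model$run
  slope <- model$cfg@leakySlope
  feats <- vector("list", model$arch$levels)
  caches <- if (withCache) list() else NULL
  cur <- x
  for (i in seq_len(model$arch$levels)) {
    nm <- paste0("block", i)
    cv <- .conv2dFwd(cur, p[[nm]]$conv$w, p[[nm]]$conv$b, 2L, 1L)
    bn <- bnFwd(cv, p[[nm]]$bn$g, p[[nm]]$bn$b, run[[nm]], train)
    run[[nm]] <- bn$run
    y <- lreluFwd(bn$y, slope)
    if (withCache) caches[[nm]] <- list(x = cur, bn = bn$cache, bny = bn$y)
    feats[[i]] <- y
    cur <- y
  }
  list(features = feats, cache = caches, run = run)
}

# Backward through the critic from per-scale feature gradients.
backwardCritic <- function(model, cache, dfeats, needDx = FALSE) {
  p <- model$params
  slope <- model$cfg@leakySlope
  grads <- list()
  dcur <- NULL
  for (i in rev(seq_len(model$arch$levels))) {
    nm <- paste0("block", i)
    dy <- dfeats[[i]]
    if (!is.null(dcur)) dy <- dy + dcur
    dbn <- lreluBwd(cache[[nm]]$bny, dy, slope)
    bb <- bnBwd(cache[[nm]]$bn, dbn)
    grads[[nm]] <- list(bn = list(g = bb$dg, b = bb$db))
    cb <- .conv2dBwd(cache[[nm]]$x, p[[nm]]$conv$w, bb$dx, 2L, 1L,
                     i > 1L || needDx)
    grads[[nm]]$conv <- list(w = cb$dw, b = cb$db)
    dcur <- if (i > 1L || needDx) cb$dx else NULL
  }
  list(grads = grads, dx = dcur)
}

#' Count main-path convolution layers
#'
#' Applies the census rule: the named main-path convolutions of the
#' segmenter (two per unit level plus the 1x1 output head) or one per critic
#' block. SE bottleneck layers and 1x1 shortcut projections are auxiliary and
#' excluded.
#'
#' @param model from [buildSegmenter()] or [buildCritic()].
#' @return Integer layer count.
#' @export
convLayerCount <- function(model) length(model$arch$mainConvs)

#' Count unit levels (encoder + bridge + decoder stages)
#' @param model from [buildSegmenter()].
#' @return Integer level count.
#' @export
unitLevelCount <- function(model) model$arch$levels

#' Save / load a model
#'
#' Serializes the full model list (configuration, parameters, running
#' statistics) with R's native serialization.
#'
#' @param model a model list.
#' @param path file path (.rds).
#' @return `path` / the restored model.
#' @export
saveModel <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

#' JSON architecture summary
#'
#' Dumps the layer census and channel ladder, for inspection and for the
#' conformance tests.
#'
#' @param model a model list.
#' @param path optional output file.
#' @return JSON string, invisibly if written to `path`.
#' @export
architectureSummary <- function(model, path = NULL) {
  s <- list(kind = model$kind,
            convLayers = convLayerCount(model),
            unitLevels = unitLevelCount(model),
            mainConvs = model$arch$mainConvs)
  if (model$kind == "segmenter") {
    s$encoderWidths <- model$arch$encWidths
    s$bridgeWidth <- model$arch$bridgeWidth
  }
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
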