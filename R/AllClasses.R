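#' @import methods
NULL

# ---------------------------------------------------------------------------
# Configuration and data classes. Every user-facing object is an S4 class
# with a validity method; constructors supply the package defaults.
# ---------------------------------------------------------------------------

#' Synthetic vascular-image generator configuration
#'
#' Parameters of the branching-tree simulator that emulates the statistical
#' structure of fundus photographs: dark curvilinear vessels that bifurcate
#' with decreasing caliber, over a smoothly varying background with sensor
#' noise.
#'
#' @slot imageSize integer `(H, W)`, at least 32x32.
#' @slot nTrees number of root vessels grown per image.
#' @slot branchDepth maximum recursion level of the vessel tree.
#' @slot rootWidthPx starting vessel half-width in pixels.
#' @slot widthDecay multiplicative half-width factor per branch level, in (0,1).
#' @slot branchAngleDeg mean absolute deviation (degrees) of a child branch's
#'   direction from its parent's.
#' @slot vesselContrast fractional intensity drop of vessels relative to the
#'   local background, in (0, 1].
#' @slot illuminationGradient peak-to-trough background variation on the
#'   `[0,1]` intensity scale.
#' @slot noiseSigma standard deviation of additive Gaussian sensor noise.
#' @slot seed base RNG seed; combined with the sample index so each sample
#'   is independently reproducible.
#' @export
setClass("VesselSimConfig", representation(
  imageSize = "integer", nTrees = "integer", branchDepth = "integer",
  rootWidthPx = "numeric", widthDecay = "numeric", branchAngleDeg = "numeric",
  vesselContrast = "numeric", illuminationGradient = "numeric",
  noiseSigma = "numeric", seed = "integer"))

setValidity("VesselSimConfig", function(object) {
  msg <- character(0)
  if (length(object@imageSize) != 2 || any(object@imageSize < 32))
    msg <- c(msg, "imageSize must be (H, W) with both >= 32")
  if (object@nTrees < 0) msg <- c(msg, "nTrees must be >= 0")
  if (object@branchDepth < 1) msg <- c(msg, "branchDepth must be >= 1")
  if (object@rootWidthPx <= 0) msg <- c(msg, "rootWidthPx must be > 0")
  if (object@widthDecay <= 0 || object@widthDecay >= 1)
    msg <- c(msg, "widthDecay must be in (0,1)")
  if (object@vesselContrast <= 0 || object@vesselContrast > 1)
    msg <- c(msg, "vesselContrast must be in (0,1]")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 1)
    msg <- c(msg, "illuminationGradient must be in [0,1]")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-generator configuration
#'
#' Defaults describe a 128x128 image with two vessel trees of four branching
#' levels, root half-width 3 px decaying by 0.7 per level — a vessel density
#' comparable to fundus photographs — with moderate vessel contrast (0.35),
#' a 0.2 peak-to-trough illumination field and noise sigma 0.03.
#'
#' @param imageSize,nTrees,branchDepth,rootWidthPx,widthDecay,branchAngleDeg
#'   see [VesselSimConfig-class].
#' @param vesselContrast,illuminationGradient,noiseSigma,seed
#'   see [VesselSimConfig-class].
#' @return a validated [VesselSimConfig-class] object.
#' @examples
#' cfg <- vesselSimConfig(nTrees = 3L, seed = 7L)
#' @export
vesselSimConfig <- function(imageSize = c(128L, 128L), nTrees = 2L,
                            branchDepth = 4L, rootWidthPx = 3,
                            widthDecay = 0.7, branchAngleDeg = 30,
                            vesselContrast = 0.35,
                            illuminationGradient = 0.2, noiseSigma = 0.03,
                            seed = 1L) {
  new("VesselSimConfig", imageSize = as.integer(imageSize),
      nTrees = as.integer(nTrees), branchDepth = as.integer(branchDepth),
      rootWidthPx = rootWidthPx, widthDecay = widthDecay,
      branchAngleDeg = branchAngleDeg, vesselContrast = vesselContrast,
      illuminationGradient = illuminationGradient, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' An image with its vessel annotation
#'
#' @slot image 2-d (grayscale) or `(H, W, 3)` RGB array on `[0,1]`.
#' @slot mask 2-d binary matrix, 1 = vessel.
#' @slot roi 2-d binary matrix marking the field of view, or `NULL`.
#' @slot sampleId character identifier.
#' @export
setClass("ImageSample", representation(
  image = "array", mask = "matrix", roi = "ANY", sampleId = "character"))

setValidity("ImageSample", function(object) {
  msg <- character(0)
  di <- dim(object@image)
  dm <- dim(object@mask)
  if (!all(di[1:2] == dm))
    msg <- c(msg, "image and mask must share (H, W)")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be strictly binary")
  if (!is.null(object@roi)) {
    if (!all(dim(object@roi) == dm))
      msg <- c(msg, "roi must share (H, W) with mask")
    else if (!all(object@roi %in% c(0, 1)))
      msg <- c(msg, "roi must be strictly binary")
    else if (any(object@mask == 1 & object@roi == 0))
      msg <- c(msg, "mask must lie inside the roi")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImageSample
#'
#' @param image,mask,roi,sampleId see [ImageSample-class].
#' @return a validated [ImageSample-class] object.
#' @export
imageSample <- function(image, mask, roi = NULL, sampleId = "sample") {
  if (is.null(dim(image))) image <- as.matrix(image)
  new("ImageSample", image = as.array(image),
      mask = as.matrix(mask), roi = if (is.null(roi)) NULL else as.matrix(roi),
      sampleId = sampleId)
}

setMethod("show", "ImageSample", function(object) {
  d <- dim(object@image)
  cat("ImageSample \"", object@sampleId, "\": ", d[1], "x", d[2],
      if (length(d) == 3) paste0("x", d[3]) else "",
      ", vessel fraction ", sprintf("%.3f", mean(object@mask)),
      if (!is.null(object@roi)) ", with ROI" else "", "\n", sep = "")
})

#' Dataset manifest
#'
#' @slot entries data.frame with columns `sample_id`, `image_path`,
#'   `mask_path`, `roi_path` (NA when absent) and `split`.
#' @slot root base directory the paths are relative to.
#' @export
setClass("DatasetManifest",
         representation(entries = "data.frame", root = "character"))

setValidity("DatasetManifest", function(object) {
  msg <- character(0)
  need <- c("sample_id", "image_path", "mask_path", "roi_path", "split")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@entries$sample_id))
      msg <- c(msg, "sample_ids must be unique")
    if (!all(object@entries$split %in% c("train", "test")))
      msg <- c(msg, "split must be 'train' or 'test'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DatasetManifest", function(object) {
  cat("DatasetManifest:", nrow(object@entries), "samples (",
      sum(object@entries$split == "train"), "train /",
      sum(object@entries$split == "test"), "test ) under", object@root, "\n")
})

#' Preprocessing configuration
#'
#' Houses the enhancement chain applied before training: grayscale
#' conversion, edge-preserving bilateral smoothing, contrast-limited
#' adaptive histogram equalization (CLAHE) and gamma correction.
#'
#' @slot grayscaleMode `"luminance"` (0.299/0.587/0.114 weights) or
#'   `"green_channel"`.
#' @slot bilateralDiameter odd window diameter in pixels.
#' @slot bilateralSigmaColor range-kernel sigma on the `[0,1]` intensity scale.
#' @slot bilateralSigmaSpace spatial-kernel sigma in pixels.
#' @slot claheClipLimit histogram clip limit (dimensionless, > 0).
#' @slot claheTileGrid integer `(rows, cols)` tile grid.
#' @slot gamma exponent of the power-law intensity transform, > 0.
#' @slot enabled when `FALSE` the pipeline reduces to grayscale conversion
#'   (the ablation arm; useful for OCT-A-style data where enhancement can
#'   blur thin vessels into the background).
#' @export
setClass("PreprocessConfig", representation(
  grayscaleMode = "character", bilateralDiameter = "integer",
  bilateralSigmaColor = "numeric", bilateralSigmaSpace = "numeric",
  claheClipLimit = "numeric", claheTileGrid = "integer", gamma = "numeric",
  enabled = "logical"))

setValidity("PreprocessConfig", function(object) {
  msg <- character(0)
  if (!object@grayscaleMode %in% c("luminance", "green_channel"))
    msg <- c(msg, "grayscaleMode must be 'luminance' or 'green_channel'")
  if (object@bilateralDiameter < 1 || object@bilateralDiameter %% 2 == 0)
    msg <- c(msg, "bilateralDiameter must be a positive odd integer")
  if (object@bilateralSigmaColor <= 0 || object@bilateralSigmaSpace <= 0)
    msg <- c(msg, "bilateral sigmas must be > 0")
  if (object@claheClipLimit <= 0) msg <- c(msg, "claheClipLimit must be > 0")
  if (length(object@claheTileGrid) != 2 || any(object@claheTileGrid < 1))
    msg <- c(msg, "claheTileGrid must be (rows, cols) >= (1,1)")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a preprocessing configuration
#'
#' Defaults are common fundus-enhancement settings: bilateral diameter 9
#' with sigmas (0.1 intensity, 5 px), CLAHE clip limit 2 on an 8x8 tile
#' grid, and gamma 1.2.
#'
#' @param grayscaleMode,bilateralDiameter,bilateralSigmaColor see
#'   [PreprocessConfig-class].
#' @param bilateralSigmaSpace,claheClipLimit,claheTileGrid,gamma,enabled see
#'   [PreprocessConfig-class].
#' @return a validated [PreprocessConfig-class] object.
#' @export
preprocessConfig <- function(grayscaleMode = "luminance",
                             bilateralDiameter = 9L,
                             bilateralSigmaColor = 0.1,
                             bilateralSigmaSpace = 5,
                             claheClipLimit = 2, claheTileGrid = c(8L, 8L),
                             gamma = 1.2, enabled = TRUE) {
  new("PreprocessConfig", grayscaleMode = grayscaleMode,
      bilateralDiameter = as.integer(bilateralDiameter),
      bilateralSigmaColor = bilateralSigmaColor,
      bilateralSigmaSpace = bilateralSigmaSpace,
      claheClipLimit = claheClipLimit,
      claheTileGrid = as.integer(claheTileGrid), gamma = gamma,
      enabled = enabled)
}

#' Augmentation configuration
#'
#' @slot targetCount total number of samples after augmentation (originals
#'   included).
#' @slot rotationRangeDeg maximum absolute rotation angle in degrees.
#' @slot shiftFraction maximum absolute translation as a fraction of the
#'   image side, in `[0, 0.5]`.
#' @slot allowHflip,allowVflip whether horizontal / vertical flips are drawn.
#' @slot seed RNG seed for the random transform stream.
#' @export
setClass("AugmentConfig", representation(
  targetCount = "integer", rotationRangeDeg = "numeric",
  shiftFraction = "numeric", allowHflip = "logical", allowVflip = "logical",
  seed = "integer"))

setValidity("AugmentConfig", function(object) {
  msg <- character(0)
  if (object@targetCount < 1) msg <- c(msg, "targetCount must be >= 1")
  if (object@rotationRangeDeg < 0 || object@rotationRangeDeg > 180)
    msg <- c(msg, "rotationRangeDeg must be in [0, 180]")
  if (object@shiftFraction < 0 || object@shiftFraction > 0.5)
    msg <- c(msg, "shiftFraction must be in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Create an augmentation configuration
#'
#' Defaults: rotations up to +/-30 degrees, shifts up to +/-10% of the side,
#' horizontal and vertical flips enabled — modest, topology-preserving
#' transforms for vessel data.
#'
#' @param targetCount,rotationRangeDeg,shiftFraction see
#'   [AugmentConfig-class].
#' @param allowHflip,allowVflip,seed see [AugmentConfig-class].
#' @return a validated [AugmentConfig-class] object.
#' @export
augmentConfig <- function(targetCount, rotationRangeDeg = 30,
                          shiftFraction = 0.1, allowHflip = TRUE,
                          allowVflip = TRUE, seed = 1L) {
  new("AugmentConfig", targetCount = as.integer(targetCount),
      rotationRangeDeg = rotationRangeDeg, shiftFraction = shiftFraction,
      allowHflip = allowHflip, allowVflip = allowVflip,
      seed = as.integer(seed))
}

#' Network architecture configuration
#'
#' @slot depth number of encoder levels (>= 2); level channels double per
#'   level starting from `baseChannels`.
#' @slot baseChannels channels at the full-resolution level.
#' @slot bottleneckChannels channels after the inception fusion; defaults to
#'   the deepest encoder width.
#' @slot fusionChannels per-source width inside full-scale skip fusion.
#' @slot inChannels 1 (grayscale) or 3 (RGB).
#' @export
setClass("ModelConfig", representation(
  depth = "integer", baseChannels = "integer",
  bottleneckChannels = "integer", fusionChannels = "integer",
  inChannels = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@depth < 2) msg <- c(msg, "depth must be >= 2")
  if (object@baseChannels < 1 || object@bottleneckChannels < 1 ||
      object@fusionChannels < 1)
    msg <- c(msg, "all channel counts must be positive")
  if (!object@inChannels %in% c(1L, 3L))
    msg <- c(msg, "inChannels must be 1 or 3")
  if (length(msg)) msg else TRUE
})

#' Create an architecture configuration
#'
#' Defaults mirror standard U-Net sizing: depth 4 with 32 base channels
#' doubling per level, a bottleneck kept at the deepest encoder width, and
#' a uniform 32-channel fusion width in the full-scale skip connections.
#'
#' @param depth,baseChannels,bottleneckChannels,fusionChannels,inChannels
#'   see [ModelConfig-class].
#' @return a validated [ModelConfig-class] object.
#' @export
modelConfig <- function(depth = 4L, baseChannels = 32L,
                        bottleneckChannels = baseChannels * 2^(depth - 1),
                        fusionChannels = 32L, inChannels = 1L) {
  new("ModelConfig", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels),
      bottleneckChannels = as.integer(bottleneckChannels),
      fusionChannels = as.integer(fusionChannels),
      inChannels = as.integer(inChannels))
}

#' The segmentation network
#'
#' Holds the architecture configuration and a private environment with the
#' weight arrays, batch-norm running statistics and optimizer state. Use
#' [buildModel()] to construct, [trainModel()] to fit, and
#' [predictProbability()] to segment.
#'
#' @slot config a [ModelConfig-class] object.
#' @slot env environment of parameters and buffers.
#' @export
setClass("VesselSegModel",
         representation(config = "ModelConfig", env = "environment"))

setMethod("show", "VesselSegModel", function(object) {
  cfg <- object@config
  cat("VesselSegModel: depth", cfg@depth, ", base", cfg@baseChannels,
      "channels, bottleneck", cfg@bottleneckChannels, ", fusion width",
      cfg@fusionChannels, "\n  trainable parameters:",
      format(parameterCount(object), big.mark = ","), "\n")
})

#' Training configuration
#'
#' @slot epochs number of epochs.
#' @slot stepsPerEpoch optimizer steps per epoch.
#' @slot batchSize images per optimizer step.
#' @slot learningRate Adam step size.
#' @slot optimizer currently `"adam"`.
#' @slot loss `"bce"` (binary cross-entropy) or `"bce_plus_dice"`.
#' @slot threshold probability cutoff used when binarizing predictions.
#' @slot seed RNG seed controlling shuffling (and any loss stochasticity).
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", stepsPerEpoch = "integer", batchSize = "integer",
  learningRate = "numeric", optimizer = "character", loss = "character",
  threshold = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@epochs < 1 || object@stepsPerEpoch < 1 || object@batchSize < 1)
    msg <- c(msg, "epochs, stepsPerEpoch and batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0,1)")
  if (!object@optimizer %in% "adam")
    msg <- c(msg, "optimizer must be 'adam'")
  if (!object@loss %in% c("bce", "bce_plus_dice"))
    msg <- c(msg, "loss must be 'bce' or 'bce_plus_dice'")
  if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' Defaults follow the protocol of 100 epochs of 100 steps with binary
#' cross-entropy, Adam at learning rate 1e-3, and a 0.5 binarization
#' threshold. Scale `epochs`/`stepsPerEpoch` down for desk-scale runs.
#'
#' @param epochs,stepsPerEpoch,batchSize,learningRate,optimizer see
#'   [TrainConfig-class].
#' @param loss,threshold,seed see [TrainConfig-class].
#' @return a validated [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 100L, stepsPerEpoch = 100L, batchSize = 2L,
                        learningRate = 1e-3, optimizer = "adam",
                        loss = "bce", threshold = 0.5, seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs),
      stepsPerEpoch = as.integer(stepsPerEpoch),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      optimizer = optimizer, loss = loss, threshold = threshold,
      seed = as.integer(seed))
}

#' Pixel confusion counts
#'
#' @slot tp,fp,fn,tn pixel tallies of true/false positives/negatives.
#' @export
setClass("ConfusionCounts",
         representation(tp = "numeric", fp = "numeric", fn = "numeric",
                        tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
    "counts must be non-negative" else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP", object@tp, "FP", object@fp, "FN", object@fn,
      "TN", object@tn, "\n")
})

#' Segmentation metrics report
#'
#' The five pixel-classification statistics: accuracy, precision, recall,
#' F1 (harmonic precision/recall mean, beta = 1) and intersection-over-union.
#' Metrics whose denominator was zero are reported as 0 and listed in
#' `undefined`.
#'
#' @slot accuracy,precision,recall,f1,iou fractions in `[0,1]`.
#' @slot undefined names of metrics whose denominator was zero.
#' @export
setClass("MetricsReport", representation(
  accuracy = "numeric", precision = "numeric", recall = "numeric",
  f1 = "numeric", iou = "numeric", undefined = "character"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.1f%%  IoU %.1f%%\n",
    100 * object@accuracy, 100 * object@precision, 100 * object@recall,
    100 * object@f1, 100 * object@iou))
  if (length(object@undefined))
    cat("  undefined (zero denominator):",
        paste(object@undefined, collapse = ", "), "\n")
})
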