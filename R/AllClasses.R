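#' @import methods
NULL

#' Architecture configuration for an AID-U-Net
#'
#' An `ArchConfig` fully determines one AID-U-Net instance: the depth `K` of
#' the direct contracting/expansive path, the depth `d` of the nested
#' sub-expansive/sub-contracting excursion, the filter exponent `nf` (the
#' base filter count at the top level is `2^nf`, doubling at every
#' contracting step), the spatial dimensionality, the channel/class counts,
#' the per-axis input (patch) extent and the in-block dropout rate.
#' `d = 0` degenerates to a conventional U-Net of depth `K`.
#'
#' Validity requires `0 <= d <= K` (sub-paths cannot be longer than the
#' direct path) and every axis of `inputExtent` divisible by `2^K`, so that
#' all 2x2 max-pools act on even axes.
#'
#' @slot K direct-path depth (number of down-sampling steps), positive integer.
#' @slot d sub-path depth, non-negative integer, at most `K`.
#' @slot nf base filter exponent; level-`l` blocks carry `2^(nf + l)` filters.
#' @slot dims spatial dimensionality, 2 or 3.
#' @slot inChannels number of input channels.
#' @slot numClasses number of output classes (>= 2).
#' @slot inputExtent integer per-axis spatial size of one input patch.
#' @slot dropout dropout fraction in `[0, 1)` applied at the end of each block.
#' @name ArchConfig-class
#' @aliases ArchConfig
#' @exportClass ArchConfig
setClass("ArchConfig",
  representation(
    K = "integer", d = "integer", nf = "integer", dims = "integer",
    inChannels = "integer", numClasses = "integer",
    inputExtent = "integer", dropout = "numeric"
  )
)

setValidity("ArchConfig", function(object) {
  msgs <- character()
  if (length(object@K) != 1L || is.na(object@K) || object@K < 1L)
    msgs <- c(msgs, "K must be a positive integer")
  if (length(object@d) != 1L || is.na(object@d) || object@d < 0L)
    msgs <- c(msgs, "d must be a non-negative integer")
  if (length(object@d) == 1L && length(object@K) == 1L &&
      !is.na(object@d) && !is.na(object@K) && object@d > object@K)
    msgs <- c(msgs, sprintf(
      "sub-path depth d = %d exceeds its maximum, the direct-path depth K = %d",
      object@d, object@K))
  if (length(object@nf) != 1L || is.na(object@nf) || object@nf < 1L)
    msgs <- c(msgs, "nf must be a positive integer")
  if (!(length(object@dims) == 1L && object@dims %in% c(2L, 3L)))
    msgs <- c(msgs, "dims must be 2 or 3")
  if (length(object@inChannels) != 1L || object@inChannels < 1L)
    msgs <- c(msgs, "inChannels must be a positive integer")
  if (length(object@numClasses) != 1L || object@numClasses < 2L)
    msgs <- c(msgs, "numClasses must be an integer >= 2")
  if (length(object@dropout) != 1L || is.na(object@dropout) ||
      object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must lie in [0, 1)")
  if (length(object@dims) == 1L && object@dims %in% c(2L, 3L)) {
    if (length(object@inputExtent) != object@dims) {
      msgs <- c(msgs, "inputExtent must have one entry per spatial axis")
    } else if (length(object@K) == 1L && !is.na(object@K) && object@K >= 1L) {
      div <- 2L^object@K
      bad <- which(object@inputExtent %% div != 0L)
      if (length(bad))
        msgs <- c(msgs, sprintf(
          "input extent axis %d (%d) is not divisible by 2^K = %d",
          bad[1], object@inputExtent[bad[1]], div))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ArchConfig
#'
#' @param K direct-path depth (down-sampling steps).
#' @param d sub-path depth, `0 <= d <= K`; `d = 0` is a conventional U-Net.
#' @param nf base filter exponent (the top level uses `2^nf` filters;
#'   the reference configuration uses `nf = 5`, i.e. 32 filters).
#' @param dims spatial dimensionality, 2 (images) or 3 (volumes).
#' @param inChannels input channels (3 for RGB, 1 for grayscale, ...).
#' @param numClasses number of segmentation classes, at least 2.
#' @param inputExtent per-axis patch extent; defaults to 256 per axis in 2D
#'   and 64x64x32 in 3D. Every axis must be divisible by `2^K`.
#' @param dropout dropout fraction in `[0, 1)` inside blocks.
#' @return A validated [ArchConfig-class] object.
#' @examples
#' archConfig(K = 3, d = 1)
#' archConfig(K = 2, d = 2, dims = 3, inChannels = 4, inputExtent = c(16, 16, 8))
#' @export
archConfig <- function(K, d = 0L, nf = 5L, dims = 2L, inChannels = 3L,
                       numClasses = 2L,
                       inputExtent = NULL, dropout = 0.5) {
  dims <- as.integer(dims)
  if (is.null(inputExtent))
    inputExtent <- if (identical(dims, 3L)) c(64L, 64L, 32L) else c(256L, 256L)
  new("ArchConfig",
    K = as.integer(K), d = as.integer(d), nf = as.integer(nf), dims = dims,
    inChannels = as.integer(inChannels), numClasses = as.integer(numClasses),
    inputExtent = as.integer(inputExtent), dropout = as.numeric(dropout))
}

setMethod("show", "ArchConfig", function(object) {
  cat(sprintf("AID-U-Net(%d, %d) %dD ArchConfig\n", object@K, object@d, object@dims))
  cat(sprintf("  base filters 2^%d = %d, %d -> %d channels/classes\n",
    object@nf, 2L^object@nf, object@inChannels, object@numClasses))
  cat(sprintf("  input extent %s, dropout %.2f\n",
    paste(object@inputExtent, collapse = "x"), object@dropout))
})

#' Worst-case complexity order of an AID-U-Net
#'
#' Holds the two geometric-series sums that bound the computational order of
#' an AID-U-Net: `s1` over the direct path and `s2` over the nested sub-path,
#' with `order = s1 + s2`.
#'
#' @slot K direct-path depth used.
#' @slot d sub-path depth used.
#' @slot s1 direct-path geometric sum, `2^(K+1) - 1`.
#' @slot s2 sub-path geometric sum, `2^(K+1) - 2^(K-d)`.
#' @slot order total worst-case order, `s1 + s2`.
#' @name ComplexitySummary-class
#' @aliases ComplexitySummary
#' @exportClass ComplexitySummary
setClass("ComplexitySummary",
  representation(K = "integer", d = "integer",
                 s1 = "numeric", s2 = "numeric", order = "numeric"))

setValidity("ComplexitySummary", function(object) {
  if (!isTRUE(all.equal(object@order, object@s1 + object@s2)))
    return("order must equal s1 + s2")
  if (object@s1 <= 0 || object@s2 < 0) return("sums must be positive")
  TRUE
})

setMethod("show", "ComplexitySummary", function(object) {
  cat(sprintf("AID-U-Net(%d, %d) worst-case order O(%s) [s1 = %s, s2 = %s]\n",
    object@K, object@d, format(object@order, big.mark = ","),
    format(object@s1), format(object@s2)))
})

#' Planned layer graph of a segmentation network
#'
#' The `LayerGraph` is the planner's output: an ordered block list (role,
#' level, filter count) together with a fully resolved primitive-layer table
#' (every convolution, up-convolution and batch-normalization with its
#' kernel extent and channel counts) and the block-to-block connections
#' (pools, up-convolutions, skip concatenations). Both the runnable model
#' and the exact learnable-parameter count derive from this object.
#'
#' @slot config the [ArchConfig-class] the graph was planned from.
#' @slot blocks data.frame with columns `id`, `role` (contract, sub-expand,
#'   sub-contract, expand, head), `level`, `filters`, `inChannels`.
#' @slot layers data.frame of primitive layers: `block`, `kind` (conv,
#'   upconv, bn, relu, dropout, concat, pool, softmax), `kernel`, `inCh`,
#'   `outCh`, `params`.
#' @slot connections data.frame with columns `from`, `to`, `type`
#'   (`pool`, `upconv`, `feed`, `concat-skip`).
#' @slot totalLayerCount number of primitive layers in the graph.
#' @name LayerGraph-class
#' @aliases LayerGraph
#' @exportClass LayerGraph
setClass("LayerGraph",
  representation(config = "ArchConfig", blocks = "data.frame",
                 layers = "data.frame", connections = "data.frame",
                 totalLayerCount = "integer"))

setMethod("show", "LayerGraph", function(object) {
  cfg <- object@config
  cat(sprintf("LayerGraph for AID-U-Net(%d, %d), %dD, base 2^%d filters\n",
    cfg@K, cfg@d, cfg@dims, cfg@nf))
  cat(sprintf("  %d blocks (levels %s), %d primitive layers\n",
    nrow(object@blocks), paste(object@blocks$level, collapse = ","),
    object@totalLayerCount))
  cat(sprintf("  learnable parameters: %s\n",
    formatParamCount(sum(object@layers$params))))
})

#' Crop-and-tile plan mapping an image onto fixed-size patches
#'
#' Records the object-preserving crop window chosen for one image and the
#' origins of every patch tiled inside it. Coordinates are 0-based along
#' half-open intervals, ordered (y, x) in 2D and (z, y, x) in 3D.
#' When `overlap` is `FALSE` the patches partition the crop window exactly.
#'
#' @slot imageExtent per-axis extent of the original image.
#' @slot cropOffset 0-based per-axis offset of the crop window.
#' @slot cropExtent per-axis size of the crop window.
#' @slot patchExtent per-axis patch size.
#' @slot patchOrigins integer matrix, one row per patch, 0-based offsets
#'   relative to the crop window.
#' @slot overlap logical; `TRUE` when patches must overlap to cover the window.
#' @slot clippedForeground number of foreground pixels the crop discards.
#' @name PatchPlan-class
#' @aliases PatchPlan
#' @exportClass PatchPlan
setClass("PatchPlan",
  representation(imageExtent = "integer", cropOffset = "integer",
                 cropExtent = "integer", patchExtent = "integer",
                 patchOrigins = "matrix", overlap = "logical",
                 clippedForeground = "integer"))

setValidity("PatchPlan", function(object) {
  nd <- length(object@imageExtent)
  if (length(object@cropOffset) != nd || length(object@cropExtent) != nd ||
      length(object@patchExtent) != nd)
    return("all extents must share the image dimensionality")
  if (any(object@cropOffset < 0L) ||
      any(object@cropOffset + object@cropExtent > object@imageExtent))
    return("crop window must lie inside the image")
  if (ncol(object@patchOrigins) != nd)
    return("patchOrigins must have one column per axis")
  for (i in seq_len(nrow(object@patchOrigins))) {
    o <- object@patchOrigins[i, ]
    if (any(o < 0L) || any(o + object@patchExtent > object@cropExtent))
      return(sprintf("patch %d exceeds the crop window", i))
  }
  if (!object@overlap) {
    if (any(object@cropExtent %% object@patchExtent != 0L))
      return("non-overlapping plans require the crop to tile by the patch")
  }
  TRUE
})

setMethod("show", "PatchPlan", function(object) {
  cat(sprintf("PatchPlan: image %s, crop %s @ %s, %d patch(es) of %s%s\n",
    paste(object@imageExtent, collapse = "x"),
    paste(object@cropExtent, collapse = "x"),
    paste(object@cropOffset, collapse = ","),
    nrow(object@patchOrigins),
    paste(object@patchExtent, collapse = "x"),
    if (object@overlap) " (overlapping)" else ""))
  if (object@clippedForeground > 0L)
    cat(sprintf("  warning: crop clips %d foreground pixel(s)\n",
      object@clippedForeground))
})

#' Geometric augmentation specification
#'
#' Quarter-turn rotations, axis reflections and small random integer
#' translations (reflection-padded), applied identically to image and mask.
#' Deterministic for a fixed `seed`.
#'
#' @slot rotations integer multiples of 90 degrees (subset of 1:3; the
#'   identity is always produced and need not be listed).
#' @slot reflections logical per-axis flags, ordered like the image axes.
#' @slot maxTranslationFraction largest translation per axis as a fraction
#'   of the extent, in `[0, 0.2]`; 0 disables translation.
#' @slot seed RNG seed controlling the sampled translations.
#' @name AugmentSpec-class
#' @aliases AugmentSpec
#' @exportClass AugmentSpec
setClass("AugmentSpec",
  representation(rotations = "integer", reflections = "logical",
                 maxTranslationFraction = "numeric", seed = "integer"))

setValidity("AugmentSpec", function(object) {
  if (length(object@rotations) && !all(object@rotations %in% 1:3))
    return("rotations must be quarter-turn multiples in 1:3")
  if (object@maxTranslationFraction < 0 || object@maxTranslationFraction > 0.2)
    return("maxTranslationFraction must lie in [0, 0.2]")
  TRUE
})

#' Construct an AugmentSpec
#'
#' @param rotations integer vector of quarter-turn multiples (e.g. `c(1, 2)`
#'   for 90 and 180 degrees); empty for none.
#' @param reflections logical vector of per-axis flip flags (recycled to the
#'   image dimensionality at apply time); `FALSE` for none.
#' @param maxTranslationFraction maximum per-axis shift as a fraction of the
#'   extent, in `[0, 0.2]`; one random translation is added when positive.
#' @param seed integer seed for the sampled translations.
#' @return An [AugmentSpec-class] object.
#' @export
augmentSpec <- function(rotations = integer(), reflections = FALSE,
                        maxTranslationFraction = 0, seed = 1L) {
  new("AugmentSpec", rotations = as.integer(rotations),
      reflections = as.logical(reflections),
      maxTranslationFraction = as.numeric(maxTranslationFraction),
      seed = as.integer(seed))
}

#' Training configuration
#'
#' Optimisation settings for [trainModel()]. The seed is applied before
#' weight-dependent shuffling and dropout so that identical seeds, data and
#' configuration reproduce identical histories on one machine.
#'
#' @slot epochs number of passes over the training set.
#' @slot batchSize mini-batch size.
#' @slot learningRate optimiser step size.
#' @slot optimizer `"adam"` or `"sgd"`.
#' @slot seed RNG seed for shuffling and dropout.
#' @slot loss `"generalized_dice"` or `"cross_entropy"`.
#' @slot validationFraction fraction of samples held out when the caller
#'   does not pass an explicit validation set.
#' @name TrainConfig-class
#' @aliases TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 seed = "integer", loss = "character",
                 validationFraction = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be positive")
  if (object@batchSize < 1L) return("batchSize must be positive")
  if (object@learningRate < 0) return("learningRate must be non-negative")
  if (!object@optimizer %in% c("adam", "sgd")) return("unknown optimizer")
  if (!object@loss %in% c("generalized_dice", "cross_entropy"))
    return("loss must be generalized_dice or cross_entropy")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    return("validationFraction must lie in (0, 1)")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param learningRate optimiser step size (Adam default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed RNG seed fixed before shuffling and dropout.
#' @param loss `"generalized_dice"` (default) or `"cross_entropy"`.
#' @param validationFraction held-out fraction in `(0, 1)`.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 10L, batchSize = 4L, learningRate = 1e-3,
                        optimizer = "adam", seed = 1L,
                        loss = "generalized_dice", validationFraction = 0.25) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = as.numeric(learningRate),
      optimizer = optimizer, seed = as.integer(seed), loss = loss,
      validationFraction = as.numeric(validationFraction))
}

#' Synthetic segmentation fixture specification
#'
#' Describes a seeded generator of blob-object segmentation samples that
#' mimic the statistical structure of small-lesion biomedical data: one to a
#' few compact foreground objects on a textured background, occupying a
#' small, heavily imbalanced fraction of pixels/voxels.
#'
#' @slot count number of samples.
#' @slot extent per-axis spatial size.
#' @slot dims 2 or 3.
#' @slot channels image channels (e.g. 3 for RGB, 4 for multi-channel volumes).
#' @slot objectsPerImage integer range `c(min, max)` of objects per sample.
#' @slot objectRadiusFraction range of the base object radius as a fraction
#'   of the smallest axis, in `(0, 0.5)`.
#' @slot foregroundFraction admissible range of the per-sample foreground
#'   pixel fraction, enforced by rejection sampling.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot texture background texture: `"flat"`, `"gradient"` or `"speckle"`.
#' @slot seed master seed; each sample derives its own stream from
#'   `(seed, index)`.
#' @name FixtureSpec-class
#' @aliases FixtureSpec
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(count = "integer", extent = "integer", dims = "integer",
                 channels = "integer", objectsPerImage = "integer",
                 objectRadiusFraction = "numeric",
                 foregroundFraction = "numeric", noiseSd = "numeric",
                 texture = "character", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  if (object@count < 1L) return("count must be positive")
  if (!object@dims %in% c(2L, 3L)) return("dims must be 2 or 3")
  if (length(object@extent) != object@dims)
    return("extent must have one entry per axis")
  if (length(object@objectsPerImage) != 2L ||
      object@objectsPerImage[1] < 1L ||
      object@objectsPerImage[2] < object@objectsPerImage[1])
    return("objectsPerImage must be an increasing positive range")
  r <- object@objectRadiusFraction
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 0.5 || r[2] < r[1])
    return("objectRadiusFraction must be an increasing range inside (0, 0.5)")
  f <- object@foregroundFraction
  if (length(f) != 2L || f[1] <= 0 || f[2] >= 1 || f[2] < f[1])
    return("foregroundFraction must be an increasing range inside (0, 1)")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (!object@texture %in% c("flat", "gradient", "speckle"))
    return("texture must be flat, gradient or speckle")
  TRUE
})

#' Construct a FixtureSpec
#'
#' Defaults emulate the class imbalance of polyp/cell segmentation data:
#' 1-3 compact objects covering 1-15% of the pixels against a textured
#' background.
#'
#' @param count number of samples to generate.
#' @param extent per-axis size, e.g. `c(64, 64)` or `c(32, 32, 16)`.
#' @param dims 2 or 3 (defaults to `length(extent)`).
#' @param channels image channels (default 3 in 2D, 4 in 3D).
#' @param objectsPerImage range `c(min, max)` of blob counts.
#' @param objectRadiusFraction base radius range as fraction of the shortest
#'   axis.
#' @param foregroundFraction admissible per-sample foreground fraction range.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param texture `"speckle"` (default), `"gradient"` or `"flat"` background.
#' @param seed master seed.
#' @return A [FixtureSpec-class] object.
#' @export
fixtureSpec <- function(count = 16L, extent = c(64L, 64L),
                        dims = length(extent),
                        channels = if (dims == 3L) 4L else 3L,
                        objectsPerImage = c(1L, 3L),
                        objectRadiusFraction = c(0.08, 0.22),
                        foregroundFraction = c(0.01, 0.15),
                        noiseSd = 0.05, texture = "speckle", seed = 1L) {
  new("FixtureSpec", count = as.integer(count), extent = as.integer(extent),
      dims = as.integer(dims), channels = as.integer(channels),
      objectsPerImage = as.integer(objectsPerImage),
      objectRadiusFraction = as.numeric(objectRadiusFraction),
      foregroundFraction = as.numeric(foregroundFraction),
      noiseSd = as.numeric(noiseSd), texture = texture, seed = as.integer(seed))
}

#' Segmentation evaluation scores
#'
#' Per-class and aggregate scores for one predicted/ground-truth mask pair:
#' precision, recall, F1, IoU and dice per class, plus global accuracy,
#' mean (per-class) accuracy, mean IoU, ground-truth-frequency-weighted IoU
#' and the mean boundary-F1 (BF) score. All values lie in `[0, 1]`; classes
#' absent from both masks are excluded from the means rather than scored 0.
#'
#' @slot perClass data.frame with one row per class present in either mask.
#' @slot globalAccuracy fraction of correctly labelled pixels.
#' @slot meanAccuracy mean per-class recall.
#' @slot meanIoU unweighted mean of per-class IoU.
#' @slot weightedIoU IoU weighted by ground-truth class frequency.
#' @slot meanBFScore mean per-class boundary-F1 score.
#' @slot meanDice mean per-class dice coefficient.
#' @name SegScores-class
#' @aliases SegScores
#' @exportClass SegScores
setClass("SegScores",
  representation(perClass = "data.frame", globalAccuracy = "numeric",
                 meanAccuracy = "numeric", meanIoU = "numeric",
                 weightedIoU = "numeric", meanBFScore = "numeric",
                 meanDice = "numeric"))

setMethod("show", "SegScores", function(object) {
  cat("Segmentation scores\n")
  cat(sprintf("  global accuracy %.4f | mean accuracy %.4f\n",
    object@globalAccuracy, object@meanAccuracy))
  cat(sprintf("  mean IoU %.4f | weighted IoU %.4f | mean BF %.4f | mean dice %.4f\n",
    object@meanIoU, object@weightedIoU, object@meanBFScore, object@meanDice))
  print(object@perClass, row.names = FALSE, digits = 4)
})

#' A runnable AID-U-Net model
#'
#' Wraps the materialized computation graph (an environment holding every
#' layer's weights, optimiser state and caches) together with the
#' [LayerGraph-class] it was built from. Create with [buildModel()], train
#' with [trainModel()], apply with [predictMask()].
#'
#' @slot graph the planned [LayerGraph-class].
#' @slot net environment containing the node list and run state.
#' @slot initSeed seed used for weight initialization.
#' @name AidUNetModel-class
#' @aliases AidUNetModel
#' @exportClass AidUNetModel
setClass("AidUNetModel",
  representation(graph = "LayerGraph", net = "environment", initSeed = "integer"))

setMethod("show", "AidUNetModel", function(object) {
  cfg <- object@graph@config
  cat(sprintf("AID-U-Net(%d, %d) %dD model, %s trainable parameters\n",
    cfg@K, cfg@d, cfg@dims, formatParamCount(countParameters(object))))
  cat(sprintf("  input %s x %d channels -> %d classes (init seed %d)\n",
    paste(cfg@inputExtent, collapse = "x"), cfg@inChannels, cfg@numClasses,
    object@initSeed))
})

# report a parameter count the way the comparison tables print them (2 s.f.)
formatParamCount <- function(n) {
  if (n >= 1e6) sprintf("%.1f M", signif(n / 1e6, 2))
  else if (n >= 1e3) sprintf("%.0f K", signif(n / 1e3, 3))
  else as.character(n)
}
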