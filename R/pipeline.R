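#' Save / load a model checkpoint
#'
#' `saveModel()` writes the weight arrays and normalization statistics to
#' an `.rds` file with a sidecar JSON describing the architecture, so a
#' checkpoint can be rebuilt without any R session state. `loadModel()`
#' reconstructs the model from the pair.
#'
#' @param model an [AidUNetModel-class].
#' @param path checkpoint path (`.rds`); the sidecar is `path` with a
#'   `.json` extension.
#' @return `saveModel()` returns `path` invisibly; `loadModel()` returns
#'   the rebuilt [AidUNetModel-class].
#' @export
saveModel <- function(model, path) {
  cfg <- model@graph@config
  weights <- lapply(model@net$nodes, function(nd) {
    w <- nd$params
    if (!is.null(nd$state))
      w <- c(w, list(runMean = nd$state$runMean, runVar = nd$state$runVar))
    w
  })
  saveRDS(list(weights = weights, initSeed = model@initSeed), path)
  sidecar <- sub("\\.rds$", ".json", path)
  writeLines(as.character(jsonlite::toJSON(list(
    K = cfg@K, d = cfg@d, nf = cfg@nf, dims = cfg@dims,
    in_channels = cfg@inChannels, num_classes = cfg@numClasses,
    input_extent = cfg@inputExtent, dropout = cfg@dropout
  ), auto_unbox = TRUE, pretty = TRUE)), sidecar)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  sidecar <- sub("\\.rds$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfg <- archConfig(K = meta$K, d = meta$d, nf = meta$nf, dims = meta$dims,
                    inChannels = meta$in_channels,
                    numClasses = meta$num_classes,
                    inputExtent = meta$input_extent, dropout = meta$dropout)
  ck <- readRDS(path)
  model <- buildModel(planLayers(cfg), seed = ck$initSeed)
  for (i in seq_along(model@net$nodes)) {
    nd <- model@net$nodes[[i]]
    w <- ck$weights[[i]]
    if (!length(nd$params)) next
    for (nm in names(nd$params)) nd$params[[nm]] <- w[[nm]]
    if (!is.null(nd$state)) {
      nd$state$runMean <- w$runMean
      nd$state$runVar <- w$runVar
    }
  }
  model
}

#' Run the full segmentation pipeline
#'
#' Executes synth/load, preprocessing (crop + patch + optional
#' augmentation), training, prediction and evaluation as configured, and
#' writes every artifact (checkpoint, history CSV, per-image scores CSV,
#' predicted masks, 2D confusion overlays, run manifest) under
#' `config$paths$out`. With `dryRun = TRUE` only the resolved architecture
#' (layer-graph JSON) and patch-plan summary are printed and nothing is
#' written.
#'
#' @param config configuration list as returned by [readRunConfig()], or a
#'   path to a YAML/JSON file.
#' @param dryRun print the plan and write nothing.
#' @return Invisibly, a list of artifact paths (empty for a dry run).
#' @export
runPipeline <- function(config, dryRun = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- as.integer(config$seed %||% 1L)
  a <- config$arch
  arch <- stage("configure", archConfig(
    K = a$k, d = a$d %||% 0L, nf = a$nf %||% 5L, dims = a$dims %||% 2L,
    inChannels = a$in_channels %||% 3L, numClasses = a$num_classes %||% 2L,
    inputExtent = a$patch_extent, dropout = a$dropout %||% 0.5))
  graph <- planLayers(arch)

  data <- stage("data", loadOrSynthesize(config, arch, seed))
  plans <- stage("preprocess", lapply(data, function(s)
    planPatches(spatialExtent(s$image, arch@dims), arch@inputExtent, s$mask,
                cropOverride = cropOverrideOf(config))))
  if (dryRun) {
    cat(as.character(layerGraphJSON(graph)), "\n")
    cat(sprintf("%d input image(s); patch plans:\n", length(plans)))
    for (p in plans) show(p)
    return(invisible(list()))
  }
  outDir <- config$paths$out %||% stop("config$paths$out is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  pairs <- stage("preprocess", {
    ps <- list()
    for (i in seq_along(data))
      ps <- c(ps, extractPatches(data[[i]]$image, data[[i]]$mask, plans[[i]]))
    pp <- config$preprocess
    if (!is.null(pp) && (length(pp$augment_rotations) ||
                         isTRUE(any(unlist(pp$augment_reflections))) ||
                         (pp$augment_translation %||% 0) > 0)) {
      ps <- augmentPairs(ps, augmentSpec(
        rotations = pp$augment_rotations %||% integer(),
        reflections = pp$augment_reflections %||% FALSE,
        maxTranslationFraction = pp$augment_translation %||% 0,
        seed = seed))
    }
    ps
  })

  t <- config$train %||% list()
  tc <- trainConfig(
    epochs = t$epochs %||% 10L, batchSize = t$batch_size %||% 4L,
    learningRate = t$learning_rate %||% 1e-3,
    optimizer = t$optimizer %||% "adam", seed = t$seed %||% seed,
    loss = t$loss %||% "generalized_dice",
    validationFraction = t$validation_fraction %||% 0.25)
  model <- stage("train", {
    m <- buildModel(graph, seed = seed)
    trainModel(m, pairs, tc)
  })
  history <- model$history
  model <- model$model

  artifacts <- list(
    checkpoint = file.path(outDir, "model.rds"),
    history = file.path(outDir, "history.csv"),
    scores = file.path(outDir, "scores.csv"),
    manifest = file.path(outDir, "manifest.json"))
  saveModel(model, artifacts$checkpoint)
  utils::write.csv(history, artifacts$history, row.names = FALSE)

  scoreRows <- stage("eval", lapply(seq_along(data), function(i) {
    pred <- predictMask(model, data[[i]]$image, plans[[i]])
    predDir <- file.path(outDir, "pred")
    dir.create(predDir, showWarnings = FALSE)
    if (arch@dims == 2L) {
      writeMaskFile(pred, file.path(predDir, sprintf("sample_%03d.png", i)))
      if (arch@numClasses == 2L) {
        ovDir <- file.path(outDir, "overlays")
        dir.create(ovDir, showWarnings = FALSE)
        writeImageFile(renderOverlay(pred, data[[i]]$mask),
                       file.path(ovDir, sprintf("sample_%03d.png", i)))
      }
    } else {
      writeMaskFile(pred, file.path(predDir, sprintf("sample_%03d.nii", i)))
    }
    s <- segmentationScores(pred, data[[i]]$mask,
                            bfTolerance = config$metrics$bf_tolerance)
    data.frame(sample = i, globalAccuracy = s@globalAccuracy,
               meanAccuracy = s@meanAccuracy, meanIoU = s@meanIoU,
               weightedIoU = s@weightedIoU, meanBFScore = s@meanBFScore,
               meanDice = s@meanDice,
               foregroundIoU = fgIoUOf(s))
  }))
  utils::write.csv(do.call(rbind, scoreRows), artifacts$scores,
                   row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(list(
    seed = seed, config = config,
    parameters = countParameters(graph),
    packageVersion = as.character(utils::packageVersion("aidunet"))
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)), artifacts$manifest)
  invisible(artifacts)
}

fgIoUOf <- function(s) {
  fg <- s@perClass$class > 0
  if (!any(fg)) return(NA_real_)
  mean(s@perClass$iou[fg], na.rm = TRUE)
}

cropOverrideOf <- function(config) {
  pp <- config$preprocess
  if (is.null(pp) || is.null(pp$crop_extent)) return(NULL)
  list(offset = pp$crop_offset %||% 0L, extent = pp$crop_extent)
}

loadOrSynthesize <- function(config, arch, seed) {
  p <- config$paths
  if (!is.null(p) && !is.null(p$images)) {
    imgs <- sort(list.files(p$images, full.names = TRUE,
                            pattern = "\\.(png|tif|tiff|nii|nii\\.gz)$"))
    msks <- sort(list.files(p$masks, full.names = TRUE,
                            pattern = "\\.(png|tif|tiff|nii|nii\\.gz)$"))
    if (!length(imgs) || length(imgs) != length(msks))
      stop("paths$images and paths$masks must hold matching file sets",
           call. = FALSE)
    return(Map(function(im, mk) list(image = readImageFile(im),
                                     mask = readMaskFile(mk)), imgs, msks))
  }
  sy <- config$synth
  if (is.null(sy)) stop("either paths$images or a synth section is required",
                        call. = FALSE)
  spec <- fixtureSpec(
    count = sy$count %||% 16L,
    extent = sy$extent %||% arch@inputExtent,
    channels = sy$channels %||% arch@inChannels,
    objectsPerImage = c(sy$objects_min %||% 1L, sy$objects_max %||% 3L),
    objectRadiusFraction = sy$radius_fraction %||% c(0.08, 0.22),
    foregroundFraction = sy$foreground_fraction %||% c(0.01, 0.15),
    noiseSd = sy$noise_sd %||% 0.05,
    texture = sy$texture %||% "speckle",
    seed = seed)
  makeDataset(spec)$samples
}

`%||%` <- function(a, b) if (is.null(a)) b else a
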