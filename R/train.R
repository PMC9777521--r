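#' Train a model
#'
#' Mini-batch optimisation of an [AidUNetModel-class] on a list of
#' `(image, mask)` samples whose extent matches the model's input contract.
#' The loss is the generalized dice loss on the softmax probabilities by
#' default (cross-entropy optionally). The configuration seed is applied
#' before shuffling and dropout, so identical seeds, data and configuration
#' reproduce identical histories on one machine. Training aborts with a
#' diagnostic naming the epoch and batch if the loss becomes non-finite.
#'
#' @param model an [AidUNetModel-class] from [buildModel()].
#' @param dataset list of `list(image =, mask =)` training samples; images
#'   are `(extent..., channels)` arrays, masks `(extent...)` integer arrays
#'   with labels `0 .. numClasses - 1`.
#' @param config a [TrainConfig-class].
#' @param valData optional explicit validation samples; when `NULL`,
#'   `config@validationFraction` of `dataset` is held out (seeded).
#' @return A list with `model` (weights updated in place) and `history`, a
#'   data.frame with one row per epoch: training/validation loss and
#'   training/validation foreground IoU.
#' @seealso [predictMask()] to apply the trained model.
#' @export
trainModel <- function(model, dataset, config, valData = NULL) {
  validObject(config)
  cfg <- model@graph@config
  net <- model@net
  nsp <- prod(cfg@inputExtent)
  M <- cfg@numClasses
  if (is.null(valData)) {
    split <- makeTrainValSplit(dataset, 1 - config@validationFraction,
                               seed = config@seed)
    trainData <- split$train
    valData <- split$val
  } else {
    trainData <- dataset
  }
  checkSample <- function(s) {
    ext <- spatialExtent(s$image, cfg@dims)
    if (!identical(as.integer(ext), cfg@inputExtent))
      stop("sample extent does not match the model input extent",
           call. = FALSE)
  }
  lapply(trainData, checkSample)
  lapply(valData, checkSample)

  lossFn <- if (config@loss == "generalized_dice") gdlWithGrad else ceWithGrad
  set.seed(config@seed)
  history <- vector("list", config@epochs)
  for (epoch in seq_len(config@epochs)) {
    ord <- sample.int(length(trainData))
    starts <- seq(1L, length(ord), by = config@batchSize)
    epochLoss <- 0; nb <- 0L
    conf <- c(I = 0, U = 0)                         # foreground IoU tallies
    for (bi in seq_along(starts)) {
      take <- ord[starts[bi]:min(starts[bi] + config@batchSize - 1L,
                                 length(ord))]
      X <- stackBatch(lapply(trainData[take], `[[`, "image"), nsp,
                      cfg@inChannels)
      labels <- unlist(lapply(trainData[take], function(s)
        as.integer(s$mask)))
      G <- oneHot(labels, M)
      P <- forwardNet(net, X, length(take), train = TRUE)
      lr <- lossFn(P, G)
      if (!is.finite(lr$loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi),
             call. = FALSE)
      backwardNet(net, lr$dP)
      optimStep(net, config@learningRate, config@optimizer)
      epochLoss <- epochLoss + lr$loss; nb <- nb + 1L
      pred <- max.col(P, ties.method = "first") - 1L
      conf <- conf + c(I = sum(pred > 0 & labels > 0),
                       U = sum(pred > 0 | labels > 0))
    }
    val <- evaluateSet(model, valData, lossFn, nsp, M, cfg)
    history[[epoch]] <- data.frame(
      epoch = epoch, trainLoss = epochLoss / nb, valLoss = val$loss,
      trainIoU = if (conf["U"] > 0) unname(conf["I"] / conf["U"]) else NA_real_,
      valIoU = val$iou)
  }
  clearCaches(net)
  list(model = model, history = do.call(rbind, history))
}

evaluateSet <- function(model, data, lossFn, nsp, M, cfg, batchSize = 8L) {
  if (!length(data)) return(list(loss = NA_real_, iou = NA_real_))
  net <- model@net
  totLoss <- 0; nb <- 0L
  conf <- c(I = 0, U = 0)
  starts <- seq(1L, length(data), by = batchSize)
  for (s in starts) {
    take <- s:min(s + batchSize - 1L, length(data))
    X <- stackBatch(lapply(data[take], `[[`, "image"), nsp, cfg@inChannels)
    labels <- unlist(lapply(data[take], function(x) as.integer(x$mask)))
    G <- oneHot(labels, M)
    P <- forwardNet(net, X, length(take), train = FALSE)
    totLoss <- totLoss + lossFn(P, G)$loss; nb <- nb + 1L
    pred <- max.col(P, ties.method = "first") - 1L
    conf <- conf + c(I = sum(pred > 0 & labels > 0),
                     U = sum(pred > 0 | labels > 0))
  }
  list(loss = totLoss / nb,
       iou = if (conf["U"] > 0) unname(conf["I"] / conf["U"]) else NA_real_)
}
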