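#' Pixelwise confusion counts
#'
#' Counts true/false positives/negatives of `positiveClass` between two
#' aligned integer label masks. The four counts always sum to the total
#' number of pixels.
#'
#' @param pred predicted integer mask (vector, matrix or array).
#' @param gt ground-truth integer mask of identical extent.
#' @param positiveClass label treated as positive (default 1).
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
confusionCounts <- function(pred, gt, positiveClass = 1L) {
  checkAligned(pred, gt)
  p <- pred == positiveClass
  g <- gt == positiveClass
  c(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g), TN = sum(!p & !g))
}

checkAligned <- function(pred, gt) {
  dp <- if (is.null(dim(pred))) length(pred) else dim(pred)
  dg <- if (is.null(dim(gt))) length(gt) else dim(gt)
  if (!identical(dp, dg))
    stop("pred and gt extents differ", call. = FALSE)
  invisible(NULL)
}

# boundary pixels of a binary region: region pixels with a face-adjacent
# neighbour (4-connectivity in 2D, 6 in 3D) outside the region; the image
# border itself does not create boundary pixels.
boundaryCoords <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) stop("boundaryCoords expects a matrix or array", call. = FALSE)
  nd <- length(d)
  inside <- array(as.logical(mask), d)
  bnd <- array(FALSE, d)
  full <- lapply(seq_len(nd), function(k) seq_len(d[k]))
  for (a in seq_len(nd)) {
    if (d[a] < 2L) next
    for (s in c(-1L, 1L)) {
      pos <- full; nbr <- full
      if (s == 1L) {
        pos[[a]] <- seq_len(d[a] - 1L); nbr[[a]] <- 2:d[a]
      } else {
        pos[[a]] <- 2:d[a]; nbr[[a]] <- seq_len(d[a] - 1L)
      }
      insPos <- do.call(`[`, c(list(inside), pos, list(drop = FALSE)))
      insNbr <- do.call(`[`, c(list(inside), nbr, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(bnd), pos, list(drop = FALSE)))
      bnd <- do.call(`[<-`, c(list(bnd), pos, list(cur | (insPos & !insNbr))))
    }
  }
  which(bnd, arr.ind = TRUE)
}

# boundary-F1 of one class: fraction of predicted boundary pixels within
# `tol` (Euclidean) of a true boundary pixel, and vice versa, combined as F1
bfScoreClass <- function(predMask, gtMask, tol) {
  bp <- boundaryCoords(predMask)
  bg <- boundaryCoords(gtMask)
  if (nrow(bp) == 0L && nrow(bg) == 0L) return(NA_real_)
  if (nrow(bp) == 0L || nrow(bg) == 0L) return(0)
  d2 <- pairwiseSqDist(bp, bg)
  prec <- mean(apply(d2, 1L, min) <= tol^2)
  rec <- mean(apply(d2, 2L, min) <= tol^2)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

pairwiseSqDist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  outer(a2, b2, "+") - 2 * A %*% t(B)
}

#' Segmentation evaluation scores
#'
#' Computes the full metric record for a predicted/ground-truth mask pair:
#' per-class precision, recall, F1, IoU (`TP / (TP + FP + FN)`) and dice
#' (`2TP / (2TP + FP + FN)`), plus global accuracy (correct / total), mean
#' accuracy (mean per-class recall), mean IoU, ground-truth-frequency
#' weighted IoU and the mean boundary-F1 (BF) score, in which predicted and
#' true class boundaries are matched within a Euclidean distance tolerance.
#' Undefined ratios for classes absent from both masks are excluded from
#' the means rather than scored zero.
#'
#' @param pred predicted integer label mask (matrix or array).
#' @param gt aligned ground-truth mask.
#' @param bfTolerance boundary-match distance in pixels; default 0.75% of
#'   the mask diagonal (at least 1).
#' @return A [SegScores-class] object.
#' @examples
#' gt <- matrix(0L, 16, 16); gt[5:9, 5:9] <- 1L
#' pr <- matrix(0L, 16, 16); pr[5:9, 6:10] <- 1L
#' segmentationScores(pr, gt)
#' @export
segmentationScores <- function(pred, gt, bfTolerance = NULL) {
  checkAligned(pred, gt)
  d <- if (is.null(dim(gt))) length(gt) else dim(gt)
  if (is.null(bfTolerance)) bfTolerance <- max(1, ceiling(0.0075 * sqrt(sum(d^2))))
  classes <- sort(unique(c(as.vector(pred), as.vector(gt))))
  total <- length(gt)
  rows <- lapply(classes, function(cl) {
    cc <- confusionCounts(pred, gt, cl)
    tp <- cc["TP"]; fp <- cc["FP"]; fn <- cc["FN"]
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else
      if (isTRUE(prec == 0) || isTRUE(rec == 0)) 0 else NA_real_
    iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
    dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    bf <- bfScoreClass(pred == cl, gt == cl, bfTolerance)
    data.frame(class = cl, freq = (tp + fn) / total,
               precision = unname(prec), recall = unname(rec),
               f1 = unname(f1), iou = unname(iou), dice = unname(dice),
               bf = bf)
  })
  pc <- do.call(rbind, rows)
  present <- pc$freq > 0
  new("SegScores", perClass = pc,
      globalAccuracy = sum(pred == gt) / total,
      meanAccuracy = mean(pc$recall[present]),
      meanIoU = mean(pc$iou, na.rm = TRUE),
      weightedIoU = sum(pc$freq[present] * pc$iou[present]),
      meanBFScore = mean(pc$bf, na.rm = TRUE),
      meanDice = mean(pc$dice, na.rm = TRUE))
}

#' Confusion-category overlay of a binary segmentation
#'
#' Renders the classic four-colour confusion overlay: true positives cyan,
#' false positives magenta, false negatives yellow and true negatives
#' black. Both masks must be binary (labels 0/1).
#'
#' @param pred predicted binary mask (2D matrix).
#' @param gt aligned binary ground-truth mask.
#' @return Numeric array `(H, W, 3)` with RGB values in `{0, 1}`.
#' @export
renderOverlay <- function(pred, gt) {
  checkAligned(pred, gt)
  if (!all(pred %in% c(0L, 1L)) || !all(gt %in% c(0L, 1L)))
    stop("renderOverlay requires binary masks", call. = FALSE)
  if (length(dim(pred)) != 2L)
    stop("renderOverlay renders 2D masks", call. = FALSE)
  p <- pred == 1L; g <- gt == 1L
  r <- ifelse(p & !g, 1, ifelse(!p & g, 1, 0))    # magenta | yellow
  gch <- ifelse(p & g, 1, ifelse(!p & g, 1, 0))   # cyan | yellow
  b <- ifelse(p & g, 1, ifelse(p & !g, 1, 0))     # cyan | magenta
  out <- array(0, c(dim(pred), 3L))
  out[, , 1] <- r; out[, , 2] <- gch; out[, , 3] <- b
  out
}

#' Per-volume dice distribution summary
#'
#' Computes the dice coefficient `2TP / (2TP + FP + FN)` of every class for
#' every predicted/ground-truth volume pair and summarizes each class's
#' distribution the way a box plot does: median, 25th/75th percentiles,
#' whiskers at the most extreme values within 1.5 IQR of the quartiles, and
#' the outliers beyond them.
#'
#' @param predVolumes list of predicted integer label volumes.
#' @param gtVolumes list of aligned ground-truth volumes.
#' @param classes integer class labels to score (default: all labels present
#'   in the ground truth).
#' @return A list with `dice` (volumes x classes matrix) and `summary`
#'   (data.frame with `class`, `median`, `q25`, `q75`, `whiskerLow`,
#'   `whiskerHigh`, `nOutliers`).
#' @export
perVolumeDice <- function(predVolumes, gtVolumes, classes = NULL) {
  if (length(predVolumes) != length(gtVolumes) || !length(predVolumes))
    stop("need one predicted volume per ground-truth volume", call. = FALSE)
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(gtVolumes, function(v)
      unique(as.vector(v))))))
  dice <- matrix(NA_real_, length(predVolumes), length(classes),
                 dimnames = list(NULL, paste0("class", classes)))
  for (i in seq_along(predVolumes)) {
    checkAligned(predVolumes[[i]], gtVolumes[[i]])
    for (j in seq_along(classes)) {
      cc <- confusionCounts(predVolumes[[i]], gtVolumes[[i]], classes[j])
      den <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
      dice[i, j] <- if (den > 0) unname(2 * cc["TP"] / den) else NA_real_
    }
  }
  summ <- do.call(rbind, lapply(seq_along(classes), function(j) {
    x <- dice[, j]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(class = classes[j], median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, whiskerLow = NA_real_,
                        whiskerHigh = NA_real_, nOutliers = 0L))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(class = classes[j], median = q[2], q25 = q[1], q75 = q[3],
               whiskerLow = lo, whiskerHigh = hi,
               nOutliers = sum(x < lo | x > hi))
  }))
  list(dice = dice, summary = summ)
}
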