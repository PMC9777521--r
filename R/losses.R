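#' Inverse-area class weights for the generalized dice loss
#'
#' For a one-hot ground truth `G` (elements x classes) the contribution of
#' class `i` is weighted by the inverse of its squared support,
#' `w_i = 1 / sum_j G_ij^2` — for binary labels the reciprocal of the class
#' pixel count. A class absent from `G` (zero denominator) receives weight
#' 0 so it contributes nothing to the loss.
#'
#' @param G numeric matrix, elements x classes, one-hot per row.
#' @return Numeric vector of per-class weights.
#' @examples
#' G <- cbind(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 1))
#' diceWeights(G) # 0.25, 1
#' @export
diceWeights <- function(G) {
  G <- asElementMatrix(G)
  denom <- colSums(G * G)
  w <- ifelse(denom > 0, 1 / denom, 0)
  as.numeric(w)
}

#' Generalized dice loss
#'
#' The class-imbalance-robust loss used to train the segmentation networks:
#' \deqn{L = 1 - \frac{2 \sum_i w_i \sum_j P_{ij} G_{ij}}
#'                    {\sum_i w_i \sum_j (P_{ij}^2 + G_{ij}^2)}}
#' over `M` classes and `N` elements, with inverse-squared-area weights
#' `w` from [diceWeights()] when not supplied. All spatial axes (and the
#' batch) are flattened into the element axis, which generalizes the loss
#' unchanged to 3D. A small smoothing constant is added to numerator and
#' denominator to guard empty intersections; it perturbs the value by less
#' than `1e-4` on non-degenerate inputs.
#'
#' @param P predicted per-class probabilities: a matrix (elements x classes)
#'   or an array whose last axis is the class axis; per-element rows must
#'   sum to 1.
#' @param G one-hot ground truth of the same shape.
#' @param weights optional per-class weights; computed from `G` when `NULL`.
#' @param eps smoothing constant (default `1e-5`).
#' @return The scalar loss in `[0, 1]` (up to eps effects).
#' @examples
#' G <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
#' generalizedDiceLoss(G, G) # ~0
#' @export
generalizedDiceLoss <- function(P, G, weights = NULL, eps = 1e-5) {
  P <- asElementMatrix(P); G <- asElementMatrix(G)
  if (!identical(dim(P), dim(G)))
    stop("P and G must have identical shapes", call. = FALSE)
  if (all(colSums(G) == 0))
    stop("at least one class must be present in G", call. = FALSE)
  w <- if (is.null(weights)) diceWeights(G) else as.numeric(weights)
  if (length(w) != ncol(P))
    stop("one weight per class required", call. = FALSE)
  num <- sum(w * colSums(P * G))
  den <- sum(w * colSums(P * P + G * G))
  1 - (2 * num + eps) / (den + eps)
}

# loss + gradient w.r.t. P, used by the training loop (weights from G are
# treated as constants, the standard convention for this loss)
gdlWithGrad <- function(P, G, eps = 1e-5) {
  w <- diceWeights(G)
  num <- sum(w * colSums(P * G))
  den <- sum(w * colSums(P * P + G * G))
  L <- 1 - (2 * num + eps) / (den + eps)
  wG <- G * rep(w, each = nrow(G))
  wP <- P * rep(w, each = nrow(P))
  dP <- -2 * wG / (den + eps) + (2 * (2 * num + eps) / (den + eps)^2) * wP
  list(loss = L, dP = dP)
}

ceWithGrad <- function(P, G) {
  n <- nrow(P)
  Pc <- pmax(P, 1e-12)
  L <- -sum(G * log(Pc)) / n
  list(loss = L, dP = -(G / Pc) / n)
}

asElementMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d)) stop("P/G must be matrices or arrays", call. = FALSE)
  matrix(x, prod(d[-length(d)]), d[length(d)])
}
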