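# independent per-pixel loop oracles shared by the metric and acceptance tests


oracleConfusion <- function(pred, gt, cl) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == cl; g <- gt[i] == cl
    if (p && g) tp <- tp + 1L else if (p) fp <- fp + 1L
    else if (g) fn <- fn + 1L else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracleBoundary <- function(mask, cl) {
  d <- dim(mask)
  out <- NULL
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    if (mask[y, x] != cl) next
    nb <- rbind(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2],
             , drop = FALSE]
    if (any(mask[nb] != cl)) out <- rbind(out, c(y, x))
  }
  out
}

oracleBF <- function(pred, gt, cl, tol) {
  bp <- oracleBoundary(pred, cl); bg <- oracleBoundary(gt, cl)
  if (is.null(bp) && is.null(bg)) return(NA_real_)
  if (is.null(bp) || is.null(bg)) return(0)
  near <- function(A, B) {
    hits <- 0L
    for (i in seq_len(nrow(A))) {
      dmin <- min(sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2))
      if (dmin <= tol) hits <- hits + 1L
    }
    hits / nrow(A)
  }
  pr <- near(bp, bg); rc <- near(bg, bp)
  if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
}

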