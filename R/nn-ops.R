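# Low-level tensor ops for the network engine.
#
# Activations are stored as matrices of shape (B * prod(sp)) x C where rows
# are ordered sample-major and, within a sample, spatially column-major
# (first axis fastest). Convolutions are evaluated as GEMMs on gathered
# im2col matrices; the gather/scatter index sets depend only on the spatial
# extent and batch size and are cached per model.

spatialCoords <- function(sp) {
  arrayInd(seq_len(prod(sp)), .dim = sp)
}

# index set for a 3^nd "same"-padded convolution
convIndexSet <- function(sp, B) {
  nd <- length(sp); spp <- sp + 2L
  nsp <- prod(sp); npp <- prod(spp)
  strides <- cumprod(c(1L, spp[-nd]))
  crd <- spatialCoords(sp)
  offs <- as.matrix(expand.grid(rep(list(0:2), nd)))
  kk <- nrow(offs)
  IDX <- matrix(0L, nsp, kk)
  for (o in seq_len(kk)) {
    pc <- sweep(crd, 2L, offs[o, ], "+")          # 1-based padded coords
    IDX[, o] <- as.integer(1L + (pc - 1L) %*% strides)
  }
  center <- which(rowSums(offs == 1L) == nd)
  sampOff <- rep((seq_len(B) - 1L) * npp, each = nsp)
  IDXB <- IDX[rep(seq_len(nsp), times = B), , drop = FALSE] + sampOff
  list(idxb = IDXB, interior = IDXB[, center], npp = npp, kk = kk,
       B = B, nsp = nsp)
}

convForward <- function(X, W, b, ix) {
  cin <- ncol(X); cout <- length(b)
  if (is.null(ix)) {                              # 1x1 convolution
    Y <- X %*% matrix(W, cin, cout)
    return(list(Y = Y + rep(b, each = nrow(Y)), G = X))
  }
  Xp <- matrix(0, ix$B * ix$npp, cin)
  Xp[ix$interior, ] <- X
  G <- Xp[as.vector(ix$idxb), , drop = FALSE]     # (Bnsp*kk) x cin
  dim(G) <- c(ix$B * ix$nsp, ix$kk * cin)
  Y <- G %*% matrix(W, ix$kk * cin, cout)
  list(Y = Y + rep(b, each = nrow(Y)), G = G)
}

convBackward <- function(dY, G, W, ix) {
  cout <- ncol(dY)
  if (is.null(ix)) {                              # 1x1 convolution
    cin <- ncol(G)
    dW <- crossprod(G, dY)
    return(list(dW = array(dW, dim(W)), db = colSums(dY),
                dX = dY %*% t(matrix(W, cin, cout))))
  }
  cin <- ncol(G) %/% ix$kk
  Wm <- matrix(W, ix$kk * cin, cout)
  dW <- crossprod(G, dY)
  db <- colSums(dY)
  dG <- dY %*% t(Wm)
  dim(dG) <- c(ix$B * ix$nsp, ix$kk, cin)
  dXp <- matrix(0, ix$B * ix$npp, cin)
  for (o in seq_len(ix$kk)) {
    rows <- ix$idxb[, o]
    dXp[rows, ] <- dXp[rows, ] + dG[, o, , drop = TRUE]
  }
  list(dW = array(dW, dim(W)), db = db,
       dX = dXp[ix$interior, , drop = FALSE])
}

# index set for 2x2 (2x2x2) max pooling, stride 2
poolIndexSet <- function(sp, B) {
  nd <- length(sp); spo <- sp %/% 2L
  nsp <- prod(sp); nso <- prod(spo)
  strides <- cumprod(c(1L, sp[-nd]))
  crd <- spatialCoords(spo)
  offs <- as.matrix(expand.grid(rep(list(0:1), nd)))
  sampOff <- rep((seq_len(B) - 1L) * nsp, each = nso)
  idx <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    pc <- sweep(2L * (crd - 1L) + 1L, 2L, offs[o, ], "+")
    base <- as.integer(1L + (pc - 1L) %*% strides)
    idx[[o]] <- rep(base, times = B) + sampOff
  }
  list(idx = idx, nIn = B * nsp, nOut = B * nso)
}

poolForward <- function(X, px) {
  Y <- X[px$idx[[1L]], , drop = FALSE]
  amax <- matrix(1L, nrow(Y), ncol(Y))
  for (k in 2:length(px$idx)) {
    cand <- X[px$idx[[k]], , drop = FALSE]
    upd <- cand > Y                                # ties keep the first slot
    Y[upd] <- cand[upd]
    amax[upd] <- k
  }
  list(Y = Y, amax = amax)
}

poolBackward <- function(dY, amax, px, C) {
  dX <- matrix(0, px$nIn, C)
  for (k in seq_along(px$idx)) {
    m <- amax == k
    if (!any(m)) next
    g <- dY
    g[!m] <- 0
    rows <- px$idx[[k]]
    dX[rows, ] <- dX[rows, ] + g
  }
  dX
}

# index set for a 2x2 (2x2x2) stride-2 transposed convolution
upconvIndexSet <- function(sp, B) {
  nd <- length(sp); spo <- 2L * sp
  nsp <- prod(sp); nso <- prod(spo)
  strides <- cumprod(c(1L, spo[-nd]))
  crd <- spatialCoords(sp)
  offs <- as.matrix(expand.grid(rep(list(0:1), nd)))
  sampOff <- rep((seq_len(B) - 1L) * nso, each = nsp)
  idx <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    oc <- sweep(2L * (crd - 1L) + 1L, 2L, offs[o, ], "+")
    base <- as.integer(1L + (oc - 1L) %*% strides)
    idx[[o]] <- rep(base, times = B) + sampOff
  }
  list(idx = idx, nOut = B * nso)
}

upconvForward <- function(X, W, b, ux) {          # W: (2^nd, cin, cout)
  cin <- dim(W)[2]; cout <- dim(W)[3]
  Y <- matrix(0, ux$nOut, cout)
  for (t in seq_along(ux$idx))
    Y[ux$idx[[t]], ] <- X %*% matrix(W[t, , ], cin, cout)
  Y + rep(b, each = nrow(Y))
}

upconvBackward <- function(dY, X, W, ux) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), cin)
  for (t in seq_along(ux$idx)) {
    dYt <- dY[ux$idx[[t]], , drop = FALSE]
    dW[t, , ] <- crossprod(X, dYt)
    dX <- dX + dYt %*% t(matrix(W[t, , ], cin, cout))
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

bnForward <- function(X, gamma, beta, state, train, momentum = 0.9,
                      eps = 1e-5) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    v[v < 0] <- 0
    istd <- 1 / sqrt(v + eps)
    xhat <- (X - rep(mu, each = n)) * rep(istd, each = n)
    state$runMean <- momentum * state$runMean + (1 - momentum) * mu
    state$runVar <- momentum * state$runVar + (1 - momentum) * v
    cache <- list(xhat = xhat, istd = istd)
  } else {
    istd <- 1 / sqrt(state$runVar + eps)
    xhat <- (X - rep(state$runMean, each = n)) * rep(istd, each = n)
    cache <- NULL
  }
  list(Y = xhat * rep(gamma, each = n) + rep(beta, each = n), cache = cache)
}

bnBackward <- function(dY, gamma, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(cache$istd, each = n)
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

reluForward <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

reluBackward <- function(dY, X) {
  dY * (X > 0)
}

dropoutForward <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

# channel-axis concatenation: the two-input merge of the expansive blocks.
# Unlike an additive merge it leaves the per-channel variance of each source
# unchanged in the output.
concatForward <- function(A, B) cbind(A, B)

concatBackward <- function(dY, nA) {
  list(dA = dY[, seq_len(nA), drop = FALSE],
       dB = dY[, -seq_len(nA), drop = FALSE])
}

addForward <- function(A, B) A + B

softmaxForward <- function(X) {
  mx <- X[, 1L]
  for (j in seq_len(ncol(X))[-1L]) mx <- pmax(mx, X[, j])
  E <- exp(X - mx)
  E / rowSums(E)
}

softmaxBackward <- function(dY, Y) {
  Y * (dY - rowSums(dY * Y))
}
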