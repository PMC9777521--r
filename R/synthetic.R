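# Seeded synthetic segmentation fixtures: compact superellipse blobs with
# low-frequency radial perturbation on textured backgrounds, mimicking the
# small-object class imbalance of polyp/cell/tumour segmentation data.

#' Generate a synthetic segmentation dataset
#'
#' Renders `spec@count` (image, mask) samples. Each sample carries 1 to a
#' few smooth blob objects — superellipses with randomized radii,
#' elongation, orientation and a low-frequency radial boundary perturbation
#' (ellipsoids in 3D) — drawn with a distinct intensity against a flat,
#' gradient or speckle background, plus additive Gaussian noise. The mask
#' is the exact rendered object support (labels 0/1). Samples whose
#' foreground fraction falls outside `spec@foregroundFraction` are
#' rejected and redrawn (bounded attempts). Every sample derives its own
#' RNG stream from `(seed, index)`, so regeneration of any subset is
#' reproducible.
#'
#' @param spec a [FixtureSpec-class].
#' @return A list with `samples` (list of `list(image, mask)`; image is
#'   `(extent..., channels)`, mask `(extent...)`) and `manifest`
#'   (data.frame with per-sample seed, object count and foreground
#'   fraction).
#' @examples
#' ds <- makeDataset(fixtureSpec(count = 2, extent = c(32, 32), seed = 7))
#' sapply(ds$samples, function(s) mean(s$mask))
#' @export
makeDataset <- function(spec) {
  validObject(spec)
  samples <- vector("list", spec@count)
  rows <- vector("list", spec@count)
  for (i in seq_len(spec@count)) {
    sampleSeed <- deriveSeed(spec@seed, i)
    s <- renderSample(spec, sampleSeed, i)
    samples[[i]] <- s[c("image", "mask")]
    rows[[i]] <- data.frame(index = i, seed = sampleSeed,
                            objects = s$objects,
                            foregroundFraction = s$fgFraction)
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}

# independent per-sample stream; kept inside 32-bit integer range
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

renderSample <- function(spec, sampleSeed, index, maxAttempts = 200L) {
  set.seed(sampleSeed)
  ext <- spec@extent; nd <- spec@dims
  nsp <- prod(ext)
  crd <- spatialCoords(ext)
  for (attempt in seq_len(maxAttempts)) {
    nobj <- sample(spec@objectsPerImage[1]:spec@objectsPerImage[2], 1L)
    mask <- rep(FALSE, nsp)
    for (k in seq_len(nobj)) mask <- mask | blobSupport(crd, ext, spec)
    fg <- mean(mask)
    if (fg >= spec@foregroundFraction[1] && fg <= spec@foregroundFraction[2])
      break
    if (attempt == maxAttempts)
      stop(sprintf(
        "sample %d: foreground fraction [%g, %g] unattainable after %d attempts",
        index, spec@foregroundFraction[1], spec@foregroundFraction[2],
        maxAttempts), call. = FALSE)
  }
  img <- array(0, c(ext, spec@channels))
  bgBase <- background(crd, ext, spec)
  for (ch in seq_len(spec@channels)) {
    fgLevel <- stats::runif(1, 0.65, 0.9)
    bgLevel <- stats::runif(1, 0.1, 0.35)
    plane <- bgLevel + 0.2 * bgBase
    plane[mask] <- fgLevel
    if (spec@noiseSd > 0)
      plane <- plane + stats::rnorm(nsp, sd = spec@noiseSd)
    idx <- c(lapply(ext, seq_len), list(ch))
    img <- do.call(`[<-`, c(list(img), idx, list(plane)))
  }
  list(image = img, mask = array(as.integer(mask), ext),
       objects = nobj, fgFraction = mean(mask))
}

# support of one randomized superellipse blob, as a logical vector over the
# column-major spatial grid
blobSupport <- function(crd, ext, spec) {
  nd <- length(ext)
  minAx <- min(ext)
  r0 <- stats::runif(1, spec@objectRadiusFraction[1],
                     spec@objectRadiusFraction[2]) * minAx
  margin <- r0 + 1
  center <- vapply(seq_len(nd), function(a)
    stats::runif(1, min(margin, ext[a] / 2), max(ext[a] - margin, ext[a] / 2)),
    1)
  elong <- stats::runif(nd, 0.7, 1.4)
  p <- stats::runif(1, 1.6, 3)                 # superellipse exponent
  X <- sweep(crd, 2L, center, "-")
  if (nd == 2L) {
    th <- stats::runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    X <- X %*% R
  }
  X <- sweep(X, 2L, r0 * elong, "/")
  rho <- rowSums(abs(X)^p)^(1 / p)
  # low-frequency radial perturbation, 2D only (ellipsoids stay smooth in 3D)
  if (nd == 2L) {
    theta <- atan2(X[, 2L], X[, 1L])
    wig <- rep(0, length(theta))
    for (k in 2:4)
      wig <- wig + stats::runif(1, 0, 0.08) *
        cos(k * theta + stats::runif(1, 0, 2 * pi))
    rho <- rho / (1 + wig)
  }
  rho <= 1
}

background <- function(crd, ext, spec) {
  nd <- length(ext)
  switch(spec@texture,
    flat = rep(0, nrow(crd)),
    gradient = {
      g <- rowSums(sweep(crd, 2L, ext, "/")) / nd
      g - mean(g)
    },
    speckle = {
      v <- stats::runif(nrow(crd), -1, 1)
      # cheap smoothing: average each pixel with its axis neighbours
      arr <- array(v, ext)
      acc <- arr
      for (a in seq_len(nd)) {
        acc <- acc + shiftEdge(arr, a, 1L) + shiftEdge(arr, a, -1L)
      }
      as.vector(acc / (2 * nd + 1))
    })
}

shiftEdge <- function(arr, axis, s) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - s, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Split a dataset into training and validation parts
#'
#' Seeded shuffle split: disjoint, exhaustive and reproducible.
#'
#' @param dataset a list of samples (e.g. `makeDataset(spec)$samples`).
#' @param fraction fraction assigned to the training part, in `(0, 1)`.
#' @param seed RNG seed for the shuffle.
#' @return A list with `train` and `val` sample lists.
#' @export
makeTrainValSplit <- function(dataset, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  n <- length(dataset)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  ntrain <- max(1L, min(n - 1L, round(fraction * n)))
  list(train = dataset[sort(ord[seq_len(ntrain)])],
       val = dataset[sort(ord[(ntrain + 1L):n])])
}
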