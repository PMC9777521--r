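#' Plan an object-preserving crop and patch tiling
#'
#' Maps an arbitrary-size image onto fixed-size patches. When every axis of
#' the image is divisible by the patch extent no cropping is applied and
#' the patches tile the image exactly. Otherwise a crop window of per-axis
#' size `floor(extent / patch) * patch` is centred on the centroid of the
#' foreground mask (clamped to the image bounds, ties broken toward the
#' top-left) so the target object is maximally contained, and patches tile
#' that window without overlap. If the foreground bounding box is too large
#' to fit inside any single patch, cropping cannot help: the full image is
#' kept as the window and an overlapping tiling with the smallest number of
#' patches (uniform stride, overlap only where unavoidable) is returned
#' with `overlap = TRUE`.
#'
#' Foreground pixels discarded by a crop are reported as a warning and
#' recorded in the plan's `clippedForeground` slot.
#'
#' @param imageExtent integer per-axis spatial size of the image.
#' @param patchExtent integer per-axis patch size (at most `imageExtent`).
#' @param mask optional integer mask aligned to the image (`> 0` marks
#'   foreground) guiding crop placement.
#' @param cropOverride optional list with `offset` and `extent` giving an
#'   explicit crop window, replacing the automatic placement (the crop size
#'   adjustment that is tuned per dataset).
#' @return A [PatchPlan-class].
#' @examples
#' planPatches(c(256, 512), c(256, 256)) # two patches, no crop
#' @export
planPatches <- function(imageExtent, patchExtent, mask = NULL,
                       cropOverride = NULL) {
  imageExtent <- as.integer(imageExtent)
  patchExtent <- as.integer(patchExtent)
  nd <- length(imageExtent)
  if (length(patchExtent) != nd)
    stop("patchExtent must match the image dimensionality", call. = FALSE)
  if (any(patchExtent > imageExtent))
    stop(sprintf("patch extent %s exceeds image extent %s",
                 paste(patchExtent, collapse = "x"),
                 paste(imageExtent, collapse = "x")), call. = FALSE)
  if (!is.null(mask)) {
    md <- if (is.null(dim(mask))) length(mask) else dim(mask)
    if (!identical(as.integer(md), imageExtent))
      stop("mask extent does not match imageExtent", call. = FALSE)
  }

  tileOrigins <- function(windowExtent) {
    n <- windowExtent %/% patchExtent
    grids <- lapply(seq_len(nd), function(a)
      as.integer((seq_len(n[a]) - 1L) * patchExtent[a]))
    originGrid(grids)
  }

  if (!is.null(cropOverride)) {
    off <- as.integer(cropOverride$offset)
    ext <- as.integer(cropOverride$extent)
    if (any(ext %% patchExtent != 0L))
      stop("crop override extent must be a multiple of the patch extent",
           call. = FALSE)
    clipped <- clippedCount(mask, off, ext)
    return(newPlan(imageExtent, off, ext, patchExtent, tileOrigins(ext),
                   FALSE, clipped))
  }

  if (all(imageExtent %% patchExtent == 0L)) {
    return(newPlan(imageExtent, rep(0L, nd), imageExtent, patchExtent,
                   tileOrigins(imageExtent), FALSE, 0L))
  }

  fg <- if (is.null(mask)) NULL else which(mask > 0, arr.ind = TRUE)
  if (!is.null(fg) && nrow(fg) > 0L) {
    bbox <- apply(fg, 2L, range)
    bboxExtent <- bbox[2L, ] - bbox[1L, ] + 1L
    if (any(bboxExtent > patchExtent)) {
      # no patch can hold the object: keep everything, tile with overlap
      return(newPlan(imageExtent, rep(0L, nd), imageExtent, patchExtent,
                     overlapOrigins(imageExtent, patchExtent), TRUE, 0L))
    }
    centroid <- colMeans(fg) - 1         # 0-based continuous
  } else {
    centroid <- (imageExtent - 1) / 2
  }
  cropExtent <- (imageExtent %/% patchExtent) * patchExtent
  off <- ceiling(centroid - cropExtent / 2 + 0.5) - 1   # ties to top-left
  off <- pmin(pmax(as.integer(off), 0L), imageExtent - cropExtent)
  clipped <- clippedCount(mask, off, cropExtent)
  newPlan(imageExtent, off, cropExtent, patchExtent, tileOrigins(cropExtent),
          FALSE, clipped)
}

originGrid <- function(grids) {
  nd <- length(grids)
  g <- expand.grid(rev(grids))           # last axis fastest -> row-major
  m <- as.matrix(g[, rev(seq_len(nd)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

overlapOrigins <- function(windowExtent, patchExtent) {
  nd <- length(windowExtent)
  grids <- lapply(seq_len(nd), function(a) {
    L <- windowExtent[a]; p <- patchExtent[a]
    n <- as.integer(ceiling(L / p))
    if (n == 1L) return(0L)
    s <- as.integer(ceiling((L - p) / (n - 1L)))
    pmin(as.integer((seq_len(n) - 1L) * s), L - p)
  })
  originGrid(grids)
}

clippedCount <- function(mask, off, ext) {
  if (is.null(mask)) return(0L)
  nd <- length(ext)
  idx <- lapply(seq_len(nd), function(a) (off[a] + 1L):(off[a] + ext[a]))
  insideFg <- sum(do.call(`[`, c(list(mask), idx, list(drop = FALSE))) > 0)
  clipped <- as.integer(sum(mask > 0) - insideFg)
  if (clipped > 0L)
    warning(sprintf("crop clips %d foreground pixel(s)", clipped),
            call. = FALSE)
  clipped
}

newPlan <- function(imageExtent, off, ext, patch, origins, overlap, clipped) {
  new("PatchPlan", imageExtent = as.integer(imageExtent),
      cropOffset = as.integer(off), cropExtent = as.integer(ext),
      patchExtent = as.integer(patch), patchOrigins = origins,
      overlap = overlap, clippedForeground = as.integer(clipped))
}

#' Extract patches according to a plan
#'
#' Slices the image (and mask, when given) at every patch origin of the
#' plan, in the plan's row-major origin order. Pixel values are untouched;
#' masks are sliced identically.
#'
#' @param image numeric array `(extent..., channels)` or `(extent...)`.
#' @param mask optional aligned integer mask, or `NULL`.
#' @param plan a [PatchPlan-class] for this image's extent.
#' @return A list of `list(image =, mask =)` pairs (mask `NULL` when not
#'   supplied).
#' @export
extractPatches <- function(image, mask, plan) {
  nd <- length(plan@imageExtent)
  ext <- spatialExtent(image, nd)
  if (!identical(as.integer(ext), plan@imageExtent))
    stop("image extent does not match the plan", call. = FALSE)
  hasChan <- length(dim(image)) > nd
  lapply(seq_len(nrow(plan@patchOrigins)), function(i) {
    o <- plan@cropOffset + plan@patchOrigins[i, ]
    idx <- lapply(seq_len(nd), function(a) (o[a] + 1L):(o[a] + plan@patchExtent[a]))
    im <- if (hasChan)
      do.call(`[`, c(list(image), idx, list(TRUE), list(drop = FALSE)))
    else do.call(`[`, c(list(image), idx, list(drop = FALSE)))
    mk <- if (!is.null(mask))
      do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
    list(image = im, mask = mk)
  })
}

#' Geometric augmentation of patch pairs
#'
#' Applies the identity plus every enabled transform — quarter-turn
#' rotations (in the plane of the last two spatial axes), axis reflections,
#' and one seeded random integer translation with reflection padding — to
#' each (image, mask) pair. Image and mask always receive the same
#' transform; mask values are moved without interpolation, so the set of
#' label values never changes. The output holds
#' `length(pairs) * (1 + #transforms)` pairs and is deterministic for a
#' fixed seed.
#'
#' @param pairs list of `list(image =, mask =)` pairs as produced by
#'   [extractPatches()].
#' @param spec an [AugmentSpec-class].
#' @return The augmented list of pairs, input order preserved (each input
#'   followed by its transformed versions).
#' @export
augmentPairs <- function(pairs, spec) {
  validObject(spec)
  if (!length(pairs)) return(pairs)
  nd <- length(spatialExtentOfPair(pairs[[1]]))
  refl <- rep(spec@reflections, length.out = nd)
  set.seed(spec@seed)
  out <- vector("list", 0L)
  for (pair in pairs) {
    sp <- spatialExtentOfPair(pair)
    tfs <- list(list(type = "id"))
    for (k in spec@rotations) tfs <- c(tfs, list(list(type = "rot", k = k)))
    for (a in which(refl)) tfs <- c(tfs, list(list(type = "flip", axis = a)))
    if (spec@maxTranslationFraction > 0) {
      mx <- pmax(1L, floor(spec@maxTranslationFraction * sp))
      shift <- vapply(mx, function(m) sample(seq(-m, m), 1L), 1L)
      tfs <- c(tfs, list(list(type = "shift", off = shift)))
    }
    for (tf in tfs)
      out <- c(out, list(list(
        image = applyGeomTransform(pair$image, tf, nd),
        mask = if (is.null(pair$mask)) NULL else
          applyGeomTransform(pair$mask, tf, nd))))
  }
  out
}

spatialExtentOfPair <- function(pair) {
  if (!is.null(pair$mask)) dim(pair$mask) else {
    d <- dim(pair$image)
    d[-length(d)]
  }
}

applyGeomTransform <- function(arr, tf, nd) {
  switch(tf$type,
    id = arr,
    rot = rotateQuarter(arr, tf$k, nd),
    flip = flipAxis(arr, tf$axis),
    shift = translateReflect(arr, tf$off, nd))
}

flipAxis <- function(arr, axis) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# k quarter-turns in the plane of the last two spatial axes
rotateQuarter <- function(arr, k, nd) {
  a <- nd - 1L; b <- nd
  for (i in seq_len(k %% 4L)) {
    perm <- seq_along(dim(arr))
    perm[c(a, b)] <- perm[c(b, a)]
    arr <- flipAxis(aperm(arr, perm), a)
  }
  arr
}

translateReflect <- function(arr, off, nd) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  for (a in seq_len(nd)) {
    src <- seq_len(d[a]) - off[a]
    idx[[a]] <- reflectIndex(src, d[a])
  }
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# reflect out-of-range 1-based indices back into [1, n] (mirror, no edge
# repetition)
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  r <- (i - 1L) %% p
  r <- ifelse(r < 0L, r + p, r)
  as.integer(ifelse(r >= n, p - r, r) + 1L)
}
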