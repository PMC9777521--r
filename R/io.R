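# Readers/writers for the formats the pipeline touches: PNG/TIFF for 2D
# images and masks, NIfTI for 3D volumes, YAML run configurations.

#' Read a 2D image or 3D volume
#'
#' PNG and TIFF files are returned as channel-last numeric arrays
#' `(H, W, C)` with values in `[0, 1]` (grayscale becomes a single
#' channel); NIfTI files (`.nii`/`.nii.gz`) are returned as numeric arrays
#' with the NIfTI header retained in the `"nifti"` attribute so a
#' round-trip preserves the affine.
#'
#' @param path file path; format inferred from the extension.
#' @return A numeric array.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    v <- RNifti::readNifti(path)
    arr <- as.array(v)
    attr(arr, "nifti") <- RNifti::niftiHeader(v)
    return(arr)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  img
}

#' Write a 2D image or 3D volume
#'
#' @param img numeric array; `(H, W)`/`(H, W, C)` for PNG/TIFF (values
#'   clipped to `[0, 1]`), any numeric array for NIfTI.
#' @param path destination; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(img, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    png::writePNG(pmin(pmax(img, 0), 1), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  } else if (ext == "nii") {
    hdr <- attr(img, "nifti")
    attr(img, "nifti") <- NULL
    if (!is.null(hdr)) {
      RNifti::writeNifti(RNifti::asNifti(img, reference = hdr), path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(img), path)
    }
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read an integer label mask
#'
#' PNG/TIFF masks are stored as intensity `label / 255` and decoded back to
#' integer labels; NIfTI masks are read directly. Non-integer values are
#' rejected.
#'
#' @param path mask file path.
#' @return An integer array of labels.
#' @export
readMaskFile <- function(path) {
  arr <- readImageFile(path)
  hdr <- attr(arr, "nifti")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("png", "tif", "tiff")) {
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] > 1L) stop("mask files must be single-channel",
                                 call. = FALSE)
      dim(arr) <- dim(arr)[1:2]
    }
    arr <- arr * 255
  }
  lab <- round(arr)
  if (max(abs(arr - lab)) > 1e-6)
    stop("mask contains non-integer label values: ", path, call. = FALSE)
  out <- array(as.integer(lab), dim(lab))
  attr(out, "nifti") <- hdr
  out
}

#' Write an integer label mask
#'
#' @param mask integer array of labels (`<= 255` for PNG/TIFF).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeMaskFile <- function(mask, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("png", "tif", "tiff")) {
    if (max(mask) > 255L) stop("labels above 255 need NIfTI output",
                               call. = FALSE)
    writeImageFile(matrix(mask / 255, nrow(mask), ncol(mask)), path)
  } else {
    writeImageFile(mask + 0L, path)
  }
  invisible(path)
}

# allowed run-configuration keys (two levels)
runConfigSchema <- function() {
  list(
    arch = c("k", "d", "nf", "dims", "in_channels", "num_classes",
             "patch_extent", "dropout"),
    train = c("epochs", "batch_size", "learning_rate", "optimizer", "seed",
              "loss", "validation_fraction"),
    preprocess = c("augment_rotations", "augment_reflections",
                   "augment_translation", "crop_offset", "crop_extent"),
    synth = c("count", "extent", "channels", "objects_min", "objects_max",
              "radius_fraction", "foreground_fraction", "noise_sd",
              "texture"),
    paths = c("images", "masks", "out"),
    metrics = "bf_tolerance",
    seed = character())
}

#' Read and validate a run configuration
#'
#' Loads a YAML (or JSON) pipeline configuration and validates it against
#' the known key schema; unknown keys are rejected so typos fail before any
#' stage runs.
#'
#' @param path YAML/JSON file path.
#' @return The validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  schema <- runConfigSchema()
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg), names(schema))) {
    if (!is.list(cfg[[sec]])) next
    badk <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(badk))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(badk, collapse = ", ")), call. = FALSE)
  }
  if (is.null(cfg$arch)) stop("config must contain an 'arch' section",
                              call. = FALSE)
  cfg
}
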