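# Plain-format I/O: RGB images as PNG/TIFF, label masks as 16-bit TIFF,
# override rasters as single-channel PNG (codes 0 keep / 1 add / 2 remove),
# spec and config objects as JSON. Every stage output is an inspectable
# text or standard image file; no opaque binary state.

#' Read an RGB core image from PNG or TIFF
#'
#' @param path image file (.png, .tif/.tiff).
#' @param coreId,patientId identifiers; default derived from the file name.
#' @return a [CoreImage-class].
#' @export
readCoreImage <- function(path, coreId = NULL, patientId = NULL) {
  if (!file.exists(path)) dataError(paste("image file not found:", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    dataError(paste("unsupported image format:", ext,
                    "(PNG and TIFF are supported)")))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  base <- tools::file_path_sans_ext(basename(path))
  coreImage(px, coreId = if (is.null(coreId)) base else coreId,
            patientId = if (is.null(patientId)) base else patientId)
}

#' Write an RGB core image as PNG
#'
#' @param image a [CoreImage-class].
#' @param path output .png path.
#' @export
writeCoreImage <- function(image, path) {
  stopifnot(is(image, "CoreImage"))
  png::writePNG(imagePixels(image), target = path)
  invisible(path)
}

#' Write an integer label mask as 16-bit single-channel TIFF
#'
#' @param mask integer matrix (0 background, k = nest k; max 65535).
#' @param path output .tif path.
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535L)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask written by [writeLabelMask()]
#'
#' @param path .tif path.
#' @return integer matrix.
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) dataError(paste("mask file not found:", path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read an override raster from single-channel PNG
#'
#' Pixel codes: 0 = keep, 1 = add (force foreground), 2 = remove (force
#' background), stored as raw 8-bit values 0/1/2.
#'
#' @param path .png path.
#' @return integer matrix of codes.
#' @export
readOverride <- function(path) {
  if (!file.exists(path)) dataError(paste("override file not found:", path))
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  if (!all(out %in% c(0L, 1L, 2L)))
    dataError("override PNG must contain only codes 0 (keep), 1 (add), 2 (remove)")
  out
}

#' Write an override raster as single-channel PNG
#'
#' @param override integer matrix of codes 0/1/2.
#' @param path output .png path.
#' @export
writeOverride <- function(override, path) {
  stopifnot(is.matrix(override), all(override %in% c(0L, 1L, 2L)))
  png::writePNG(override / 255, target = path)
  invisible(path)
}

#' Serialize a synthetic spec or run config to JSON (and back)
#'
#' Round-trips losslessly: \code{readSpecJson(writeSpecJson(x, p))} restores
#' an identical object.
#'
#' @param spec a \code{SyntheticImageSpec}, \code{SyntheticCohortSpec} or
#'   \code{RunConfig}.
#' @param path JSON file path.
#' @export
writeSpecJson <- function(spec, path) {
  obj <- unclass(spec)
  if (!is.null(obj$covariate_effects))
    obj$covariate_effects <- as.list(obj$covariate_effects)
  obj[[".class"]] <- class(spec)[1L]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSpecJson
#' @return the restored object.
#' @export
readSpecJson <- function(path) {
  if (!file.exists(path)) dataError(paste("spec file not found:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj[[".class"]]
  obj[[".class"]] <- NULL
  switch(cls,
    SyntheticImageSpec = do.call(syntheticImageSpec, obj),
    SyntheticCohortSpec = {
      obj$covariate_effects <- unlist(obj$covariate_effects)
      do.call(syntheticCohortSpec, obj)
    },
    RunConfig = {
      obj$covariate_effects <- unlist(obj$covariate_effects)
      do.call(runConfig, obj)
    },
    dataError(paste("unknown spec class in JSON:", cls)))
}
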