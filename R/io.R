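# Image file I/O: PNG and TIFF. Integer inputs (8- or 16-bit) arrive as
# [0, 1] doubles — both readers divide by the type maximum — and output is
# clipped to [0, 1] before writing.

imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stopIO("unsupported image format '", ext, "' (use PNG or TIFF): ",
              path)
}

#' Read an input image
#'
#' Reads a PNG or TIFF image as doubles in [0, 1] (8- and 16-bit integer
#' files are scaled by their type maximum on read). An alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a .png, .tif or .tiff file.
#' @param channels `"any"` returns the file's layout (matrix for
#'   single-channel, H x W x 3 array otherwise); `"gray"` insists on or
#'   converts to a single channel (channel mean); `"color"` replicates
#'   grayscale input to three channels.
#' @return Matrix or H x W x 3 array in [0, 1].
#' @export
readInputImage <- function(path, channels = c("any", "gray", "color")) {
  channels <- match.arg(channels)
  if (!file.exists(path)) stopIO("cannot read image file: ", path)
  img <- switch(imageFormat(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3] == 2L)   # gray + alpha
    img <- img[, , 1L]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- img[, , 1L]
  if (channels == "gray" && length(dim(img)) == 3L)
    img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  if (channels == "color" && is.matrix(img))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img
}

#' Write an output image
#'
#' Clips the image into [0, 1] and writes it as PNG or TIFF (by file
#' extension). Out-of-gamut values produced by intensity substitution are
#' clipped here, at the final write stage only.
#'
#' @param img Matrix or H x W x 3 array.
#' @param path Output path ending in .png, .tif or .tiff.
#' @param bitsPerSample TIFF only: bits per sample, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
writeOutputImage <- function(img, path, bitsPerSample = 8L) {
  if (is(img, "FusionResult")) img <- fusedImage(img)
  img <- clip01(img)
  switch(imageFormat(path),
         png = png::writePNG(img, path),
         tiff = tiff::writeTIFF(img, path,
                                bits.per.sample = as.integer(bitsPerSample)))
  invisible(path)
}
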