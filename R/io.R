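# PNG raster I/O. 8-bit sRGB PNG is the interchange format; images are held
# in memory as H x W x 3 double arrays of encoded values in [0, 1].

#' Read an sRGB PNG image
#'
#' Reads an 8-bit (or 16-bit, down-converted) PNG into an H x W x 3 encoded
#' sRGB array in \[0, 1\]. Grayscale images are expanded to three identical
#' channels; an alpha channel is dropped with a warning.
#'
#' @param path path to a PNG file.
#' @return H x W x 3 numeric array of encoded sRGB values.
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 2L) {  # gray + alpha
    warning("alpha channel dropped")
    img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] == 4L) {
    warning("alpha channel dropped")
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' Write an sRGB image to an 8-bit PNG
#'
#' @param img H x W x 3 encoded sRGB array in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  .checkImage(img, "sRGB image")
  if (any(img < -1e-9) || any(img > 1 + 1e-9))
    stop("encoded sRGB values must lie in [0, 1]")
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
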