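# Color space conversions: encoded sRGB <-> linear RGB <-> CIE XYZ -> CIELAB
# and proLab. All images are H x W x 3 numeric arrays in double precision;
# 8-bit quantization happens only at file I/O.

# sRGB (IEC 61966-2-1) linear RGB -> XYZ matrix, D65 reference white.
.RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# proLab projective transform, transcribed from the proLab publication
# (Konovalenko et al., IEEE Access 9, 2021). Acts on white-normalized
# (X/Xn, Y/Yn, Z/Zn); rows 2-3 sum to zero so the gray axis maps to a+ = b+ = 0.
.PROLAB_Q <- matrix(c(
   75.5362,  486.661,   167.387,
  617.7141, -595.4477,  -22.2664,
   48.3433,  194.9377, -243.281
), nrow = 3, byrow = TRUE)
.PROLAB_q <- c(0.7554, 3.8666, 1.6739)

#' D65 reference white in CIE XYZ
#'
#' The XYZ coordinates of linear RGB (1, 1, 1) under the sRGB primaries,
#' i.e. the row sums of the sRGB RGB-to-XYZ matrix. Using the matrix's own
#' white guarantees that the gray axis maps exactly onto a = b = 0.
#'
#' @return numeric length-3 vector (Xn, Yn, Zn), Yn ~ 1.
#' @export
whitePointD65 <- function() as.vector(.RGB2XYZ %*% c(1, 1, 1))

.checkImage <- function(img, what = "image") {
  if (!is.numeric(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be a numeric H x W x 3 array")
  if (any(!is.finite(img)))
    stop(what, " contains non-finite values")
  invisible(img)
}

# Apply a 3x3 color matrix to every pixel of an H x W x 3 array.
.applyColorMatrix <- function(img, M) {
  d <- dim(img)
  out <- matrix(img, ncol = 3L) %*% t(M)
  dim(out) <- d
  out
}

#' Decode encoded sRGB to linear RGB
#'
#' Inverts the sRGB electro-optical transfer function channelwise
#' (piecewise: linear segment below 0.04045, power 2.4 above).
#'
#' @param img H x W x 3 array (or any numeric array/vector) of encoded sRGB
#'   values in \[0, 1\].
#' @return array of the same shape with scene-linear values in \[0, 1\].
#' @examples
#' srgbDecode(array(c(0, 0.5, 1), c(1, 1, 3)))
#' @export
srgbDecode <- function(img) {
  if (any(!is.finite(img)) || any(img < -1e-9) || any(img > 1 + 1e-9))
    stop("encoded sRGB values must lie in [0, 1]")
  v <- pmin(pmax(img, 0), 1)
  out <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  if (!is.null(dim(img))) dim(out) <- dim(img)
  out
}

#' Encode linear RGB to sRGB
#'
#' Applies the sRGB opto-electronic transfer function. Input must already be
#' within \[0, 1\]: tone mapping ([toneMap()]) is responsible for range
#' reduction and must precede encoding.
#'
#' @param img numeric array of linear-light values in \[0, 1\].
#' @return array of the same shape with encoded values in \[0, 1\].
#' @export
srgbEncode <- function(img) {
  if (any(!is.finite(img)) || any(img < -1e-9) || any(img > 1 + 1e-9))
    stop("linear RGB values must lie in [0, 1]; tone-map before encoding")
  v <- pmin(pmax(img, 0), 1)
  out <- ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
  if (!is.null(dim(img))) dim(out) <- dim(img)
  out
}

#' Linear RGB to CIE XYZ
#'
#' @param img H x W x 3 linear RGB array (sRGB primaries).
#' @return H x W x 3 array of D65-relative XYZ.
#' @export
linearToXYZ <- function(img) {
  .checkImage(img, "linear RGB image")
  .applyColorMatrix(img, .RGB2XYZ)
}

#' CIE XYZ to linear RGB
#'
#' @param img H x W x 3 XYZ array.
#' @return H x W x 3 linear RGB array.
#' @export
xyzToLinear <- function(img) {
  .checkImage(img, "XYZ image")
  .applyColorMatrix(img, solve(.RGB2XYZ))
}

# CIELAB companding function with the standard linear toe below (6/29)^3.
.labF <- function(t) {
  delta3 <- (6 / 29)^3
  ifelse(t > delta3, t^(1 / 3), (841 / 108) * t + 4 / 29)
}

#' CIE XYZ to CIELAB
#'
#' Standard CIELAB conversion with the piecewise cube-root companding
#' (linear toe below (6/29)^3). For in-gamut input, L of the reference white
#' is exactly 100 and the gray axis maps to a = b = 0.
#'
#' @param img H x W x 3 XYZ array.
#' @param white XYZ triple of the reference white; default [whitePointD65()].
#' @return H x W x 3 array with channels L, a, b.
#' @export
xyzToLab <- function(img, white = whitePointD65()) {
  .checkImage(img, "XYZ image")
  if (any(white <= 0)) stop("white point components must be > 0")
  fX <- .labF(img[, , 1] / white[1])
  fY <- .labF(img[, , 2] / white[2])
  fZ <- .labF(img[, , 3] / white[3])
  out <- array(0, dim(img))
  out[, , 1] <- 116 * fY - 16
  out[, , 2] <- 500 * (fX - fY)
  out[, , 3] <- 200 * (fY - fZ)
  dimnames(out) <- list(NULL, NULL, c("L", "a", "b"))
  out
}

#' CIE XYZ to proLab
#'
#' proLab is a 3-D projective transform of XYZ: each coordinate is a ratio of
#' a linear form in white-normalized XYZ to a common linear denominator.
#' Unlike CIELAB it admits chromaticity coordinates (see
#' [proLabChromaticity()]) that are exactly invariant to achromatic scaling.
#'
#' @param img H x W x 3 XYZ array.
#' @param white XYZ triple of the reference white; default [whitePointD65()].
#' @return H x W x 3 array with channels Lp, ap, bp (L+, a+, b+).
#' @export
xyzToProLab <- function(img, white = whitePointD65()) {
  .checkImage(img, "XYZ image")
  if (any(white <= 0)) stop("white point components must be > 0")
  d <- dim(img)
  xyz <- matrix(img, ncol = 3L)
  xyz <- sweep(xyz, 2L, white, "/")
  num <- xyz %*% t(.PROLAB_Q)
  den <- as.vector(xyz %*% .PROLAB_q) + 1
  out <- num / den
  dim(out) <- d
  dimnames(out) <- list(NULL, NULL, c("Lp", "ap", "bp"))
  out
}

#' proLab chromaticity coordinates
#'
#' The normalized chromatic coordinates of proLab: atilde = a+/L+,
#' btilde = b+/L+. Because every proLab coordinate is a ratio of linear forms
#' with a shared denominator, these ratios are invariant under multiplication
#' of the XYZ (equivalently, linear RGB) vector by any positive scalar.
#' Pixels with L+ = 0 (black) carry no chromaticity and map to (0, 0) by
#' convention.
#'
#' @param prolab H x W x 3 proLab array from [xyzToProLab()].
#' @return H x W x 2 array with channels atilde, btilde.
#' @export
proLabChromaticity <- function(prolab) {
  if (!is.numeric(prolab) || length(dim(prolab)) != 3L || dim(prolab)[3] != 3L)
    stop("prolab must be an H x W x 3 array")
  L <- prolab[, , 1]
  safe <- abs(L) > 1e-12
  out <- array(0, c(dim(prolab)[1:2], 2L))
  out[, , 1][safe] <- prolab[, , 2][safe] / L[safe]
  out[, , 2][safe] <- prolab[, , 3][safe] / L[safe]
  dimnames(out) <- list(NULL, NULL, c("atilde", "btilde"))
  out
}

#' Encoded sRGB to CIELAB
#'
#' Convenience composition decode -> XYZ -> Lab used by the metrics.
#'
#' @param img H x W x 3 encoded sRGB array in \[0, 1\].
#' @return H x W x 3 Lab array.
#' @export
srgbToLab <- function(img) xyzToLab(linearToXYZ(srgbDecode(.checkImage(img))))

#' Linear RGB to proLab chromaticity
#'
#' @param img H x W x 3 linear RGB array (non-negative; values above 1 are
#'   legal here, as achromatic weighting can exceed the display range before
#'   tone mapping).
#' @return H x W x 2 chromaticity array.
#' @export
linearToProLabChromaticity <- function(img) {
  .checkImage(img, "linear RGB image")
  if (any(img < -1e-9)) stop("linear RGB image must be non-negative")
  proLabChromaticity(xyzToProLab(linearToXYZ(pmax(img, 0))))
}
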