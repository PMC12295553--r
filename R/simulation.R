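# Vienot linear dichromacy simulation in linear RGB. The matrices are
# rank-2 projections of the RGB cube onto the color plane visible to the
# dichromat; they fix black, white, the gray axis, pure blue and yellow.

.CVD_MATRICES <- list(
  protan = matrix(c(
    0.1124,  0.8876, 0,
    0.1124,  0.8876, 0,
    0.0040, -0.0040, 1
  ), nrow = 3, byrow = TRUE),
  deutan = matrix(c(
     0.2928, 0.7072, 0,
     0.2928, 0.7072, 0,
    -0.0223, 0.0223, 1
  ), nrow = 3, byrow = TRUE)
)

#' Simulation matrix for a dichromat type
#'
#' Returns the linear-RGB projection matrix modelling protanope or
#' deuteranope color perception (Vienot's simulation, built for the sRGB
#' primaries and reference white). The matrix is a compiled-in constant; the
#' factorization through LMS cone space is not recomputed.
#'
#' @param cvd `"protan"` or `"deutan"`. Tritanopia is not supported.
#' @return a [CVDMatrix-class].
#' @examples
#' simulationMatrix("protan")
#' @export
simulationMatrix <- function(cvd = c("protan", "deutan")) {
  if (length(cvd) != 1L || !cvd %in% names(.CVD_MATRICES))
    stop("unsupported CVD type; supported types: ",
         paste(names(.CVD_MATRICES), collapse = ", "))
  new("CVDMatrix", type = cvd, M = .CVD_MATRICES[[cvd]])
}

.asCVDMatrix <- function(cvd) {
  if (is(cvd, "CVDMatrix")) cvd else simulationMatrix(cvd)
}

#' Simulate dichromat perception in linear RGB
#'
#' Per-pixel matrix-vector product with the simulation matrix. No clipping is
#' applied: the third row of each matrix has a small negative entry, so
#' values may leave \[0, 1\] slightly; they are clipped only at encode time.
#'
#' @param img H x W x 3 linear RGB array.
#' @param cvd `"protan"`, `"deutan"`, or a [CVDMatrix-class].
#' @return H x W x 3 linear RGB array as seen by the dichromat.
#' @export
simulateLinear <- function(img, cvd) {
  .checkImage(img, "linear RGB image")
  .applyColorMatrix(img, as.matrix(.asCVDMatrix(cvd)))
}

#' Simulate dichromat perception of an encoded sRGB image
#'
#' decode -> [simulateLinear()] -> clip to \[0, 1\] -> encode. Grayscale,
#' blue, and yellow content is returned unchanged (up to 8-bit quantization
#' when written to file).
#'
#' @param img H x W x 3 encoded sRGB array in \[0, 1\].
#' @inheritParams simulateLinear
#' @return H x W x 3 encoded sRGB array in \[0, 1\].
#' @export
simulateSRGB <- function(img, cvd) {
  .checkImage(img, "sRGB image")
  lin <- simulateLinear(srgbDecode(img), cvd)
  srgbEncode(pmin(pmax(lin, 0), 1))
}
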