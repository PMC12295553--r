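# Synthetic fixtures with known behavior under dichromat simulation:
# confusion-contrast images whose region colors differ along the kernel
# (null-space) direction of the simulation matrix - indistinguishable to the
# target dichromat - plus control images (grayscale, blue-yellow, noise)
# that simulation leaves essentially unchanged.

#' Kernel (confusion) direction of a simulation matrix
#'
#' The unit null-space vector of the rank-2 simulation matrix: colors
#' differing by a multiple of this vector are indistinguishable to the
#' corresponding dichromat. Oriented so that the red component is positive.
#'
#' @param D a [CVDMatrix-class] or CVD type string.
#' @return unit length-3 numeric vector n with `||D n|| < 1e-12`.
#' @examples
#' kernelDirection("protan")
#' @export
kernelDirection <- function(D) {
  M <- as.matrix(.asCVDMatrix(D))
  sv <- svd(M)
  if (sv$d[3] > 1e-8) stop("matrix is not singular; no confusion direction")
  n <- sv$v[, 3]
  if (n[1] < 0) n <- -n
  n / sqrt(sum(n^2))
}

.regionLayout <- function(layout, h, w, cellSize) {
  switch(layout,
    checkerboard = {
      ri <- (seq_len(h) - 1L) %/% cellSize
      ci <- (seq_len(w) - 1L) %/% cellSize
      outer(ri, ci, "+") %% 2L == 0L
    },
    `two-region` = {
      m <- matrix(FALSE, h, w)
      m[, seq_len(w %/% 2L)] <- TRUE
      m
    },
    ramp = NULL,  # handled separately (continuous)
    stop("unknown layout: ", layout)
  )
}

#' Generate a confusion-contrast test image
#'
#' Builds an sRGB image whose regions alternate between
#' `base +/- (amplitude / 2) * n` in linear RGB, where n is the kernel
#' direction of the simulation matrix for `cvd`. By construction the two
#' region colors simulate to the same color: the image is uniform for the
#' target dichromat, i.e. its red-green contrast is fully lost.
#'
#' @param cvd `"protan"` or `"deutan"`.
#' @param base linear RGB base color (default mid-gray).
#' @param amplitude total step along the kernel direction (default 0.6).
#' @param layout `"checkerboard"`, `"two-region"`, or `"ramp"` (a continuous
#'   sweep from `-amplitude/2` to `+amplitude/2` across columns).
#' @param size c(H, W), default c(128, 128).
#' @param cellSize checkerboard cell edge in pixels (default 16).
#' @return list with `image` (encoded sRGB array), `mask` (logical H x W
#'   region indicator; for `"ramp"`, columns right of center), and `colors`
#'   (2 x 3 matrix of the two linear region colors; for `"ramp"`, the
#'   extremes).
#' @export
makeConfusionImage <- function(cvd, base = c(0.5, 0.5, 0.5), amplitude = 0.6,
                               layout = c("checkerboard", "two-region", "ramp"),
                               size = c(128L, 128L), cellSize = 16L) {
  layout <- match.arg(layout)
  if (amplitude <= 0) stop("amplitude must be > 0")
  n <- kernelDirection(cvd)
  cA <- base + (amplitude / 2) * n
  cB <- base - (amplitude / 2) * n
  if (any(c(cA, cB) < 0) || any(c(cA, cB) > 1))
    stop("region colors leave the RGB gamut; use a smaller amplitude ",
         "or a base color closer to mid-gray")
  h <- size[1]; w <- size[2]
  lin <- array(0, c(h, w, 3L))
  if (layout == "ramp") {
    t <- seq(-amplitude / 2, amplitude / 2, length.out = w)
    for (ch in 1:3)
      lin[, , ch] <- matrix(base[ch] + t * n[ch], h, w, byrow = TRUE)
    mask <- matrix(rep(seq_len(w) > w / 2, each = h), h, w)
  } else {
    mask <- .regionLayout(layout, h, w, cellSize)
    for (ch in 1:3)
      lin[, , ch] <- ifelse(mask, cA[ch], cB[ch])
  }
  list(image = srgbEncode(lin), mask = mask, colors = rbind(A = cA, B = cB))
}

#' Generate a control image unaffected by red-green dichromacy
#'
#' Controls exercise the near-fixed points of the simulation: grayscale and
#' blue-yellow content is retained by both the protan and deutan projections.
#'
#' @param kind `"grayscale-ramp"` (horizontal lightness ramp),
#'   `"blue-yellow"` (two-region blue vs yellow image), or `"random-noise"`
#'   (seeded uniform sRGB noise).
#' @param size c(H, W), default c(128, 128).
#' @param seed integer seed (used by `"random-noise"`).
#' @return H x W x 3 encoded sRGB array.
#' @export
makeControlImage <- function(kind = c("grayscale-ramp", "blue-yellow",
                                      "random-noise"),
                             size = c(128L, 128L), seed = 1L) {
  kind <- match.arg(kind)
  h <- size[1]; w <- size[2]
  img <- array(0, c(h, w, 3L))
  if (kind == "grayscale-ramp") {
    ramp <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
    for (ch in 1:3) img[, , ch] <- ramp
  } else if (kind == "blue-yellow") {
    lin <- array(0, c(h, w, 3L))
    left <- seq_len(w %/% 2L)
    blue <- c(0.08, 0.08, 0.85)
    yellow <- c(0.85, 0.85, 0.08)
    for (ch in 1:3) {
      lin[, left, ch] <- blue[ch]
      lin[, setdiff(seq_len(w), left), ch] <- yellow[ch]
    }
    img <- srgbEncode(lin)
  } else {
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(
      if (is.null(oldSeed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", oldSeed, envir = globalenv())
    )
    set.seed(seed)
    img <- array(stats::runif(h * w * 3L), c(h, w, 3L))
  }
  img
}
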