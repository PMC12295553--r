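# Local-contrast machinery: Di Zenzo structure tensor, pseudo-gradient,
# channel-sum guiding field and neighbor pair differences. The tensor and
# pseudo-gradient are diagnostic operations; the daltonization hot path works
# directly on pairwise color differences.

# Finite differences along rows (di) and columns (dj) of a matrix:
# central differences in the interior, one-sided at the borders.
.diffRows <- function(m) {
  h <- nrow(m)
  d <- matrix(0, h, ncol(m))
  if (h >= 3L) d[2:(h - 1L), ] <- (m[3:h, ] - m[1:(h - 2L), ]) / 2
  if (h >= 2L) {
    d[1L, ] <- m[2L, ] - m[1L, ]
    d[h, ] <- m[h, ] - m[h - 1L, ]
  }
  d
}
.diffCols <- function(m) t(.diffRows(t(m)))

#' Di Zenzo structure tensor of a multi-channel image
#'
#' Per-pixel 2x2 symmetric tensor S = J^T J, where J is the finite-difference
#' Jacobian of the image (central differences in the interior, one-sided at
#' borders). Its largest eigenvalue generalizes the squared gradient
#' magnitude to multi-channel images.
#'
#' @param img H x W x C numeric array (C >= 1) or an H x W matrix.
#' @return list of H x W matrices `sii`, `sij`, `sjj` (tensor components;
#'   i = row direction, j = column direction), with class
#'   `"StructureTensor"`.
#' @export
structureTensor <- function(img) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (!is.numeric(img) || length(dim(img)) != 3L || dim(img)[3] < 1L)
    stop("img must be an H x W x C array with C >= 1")
  h <- dim(img)[1]; w <- dim(img)[2]
  sii <- sij <- sjj <- matrix(0, h, w)
  for (c in seq_len(dim(img)[3])) {
    di <- .diffRows(img[, , c])
    dj <- .diffCols(img[, , c])
    sii <- sii + di * di
    sij <- sij + di * dj
    sjj <- sjj + dj * dj
  }
  structure(list(sii = sii, sij = sij, sjj = sjj),
            class = "StructureTensor")
}

# Largest eigenvalue and unit eigenvector of the 2x2 symmetric tensor,
# in closed form, vectorized over pixels.
.tensorEigenMax <- function(S) {
  tr <- S$sii + S$sjj
  disc <- sqrt(pmax((S$sii - S$sjj)^2 + 4 * S$sij^2, 0))
  lmax <- (tr + disc) / 2
  # Eigenvector: pick the numerically stabler of the two equivalent forms.
  vi1 <- lmax - S$sjj; vj1 <- S$sij
  vi2 <- S$sij;        vj2 <- lmax - S$sii
  use2 <- (vi1^2 + vj1^2) < (vi2^2 + vj2^2)
  vi <- ifelse(use2, vi2, vi1)
  vj <- ifelse(use2, vj2, vj1)
  nrm <- sqrt(vi^2 + vj^2)
  zero <- nrm < 1e-15
  vi <- ifelse(zero, 0, vi / pmax(nrm, 1e-300))
  vj <- ifelse(zero, 0, vj / pmax(nrm, 1e-300))
  list(lambda = lmax, vi = vi, vj = vj)
}

#' Channel-sum guiding field
#'
#' The scalar image formed by summing the channels of the original image. Its
#' per-pair sign differences orient the pseudo-gradient and select quadratic
#' roots during daltonization.
#'
#' @param img H x W x C numeric array.
#' @return H x W matrix of channel sums.
#' @export
guidingField <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is.numeric(img) || length(dim(img)) != 3L)
    stop("img must be an H x W x C array")
  g <- img[, , 1]
  for (c in seq_len(dim(img)[3])[-1]) g <- g + img[, , c]
  g
}

#' Guiding signs of neighbor pairs
#'
#' For each horizontal pair (p at (x, y), q at (x + d, y)) and vertical pair
#' (q at (x, y + d)), the sign of g_p - g_q where g is the channel-sum
#' guiding field. Antisymmetric by construction.
#'
#' @param g H x W guiding field matrix (from [guidingField()]).
#' @param distance positive integer pair offset (default 1).
#' @return list with `sh` (H x (W - d) matrix) and `sv` ((H - d) x W matrix)
#'   of values in \{-1, 0, +1\}.
#' @export
guidingSigns <- function(g, distance = 1L) {
  d <- as.integer(distance)
  h <- nrow(g); w <- ncol(g)
  if (d < 1L || (d >= w && d >= h))
    stop("distance out of range for image size")
  sh <- if (d < w)
    sign(g[, 1:(w - d), drop = FALSE] - g[, (1 + d):w, drop = FALSE])
  else matrix(0, h, 0L)
  sv <- if (d < h)
    sign(g[1:(h - d), , drop = FALSE] - g[(1 + d):h, , drop = FALSE])
  else matrix(0, 0L, w)
  list(sh = sh, sv = sv)
}

#' Pseudo-gradient of a multi-channel image
#'
#' The pseudo-gradient at each pixel is +/- sqrt(lambda_max) times the
#' principal eigenvector of the structure tensor; the sign is chosen so that
#' the vector has a non-negative dot product with the gradient of the guiding
#' field. When the guide gradient is orthogonal to the eigenvector (or zero),
#' the representative with non-negative row component is returned (ties on
#' that broken toward non-negative column component) - a deterministic
#' convention; the daltonization path never consumes this tie-break.
#'
#' @param S a `"StructureTensor"` from [structureTensor()].
#' @param guide H x W guiding field matrix.
#' @return H x W x 2 array; slices are the row (i) and column (j) components.
#' @export
pseudoGradient <- function(S, guide) {
  if (!inherits(S, "StructureTensor")) stop("S must be a StructureTensor")
  e <- .tensorEigenMax(S)
  mag <- sqrt(pmax(e$lambda, 0))
  gi <- .diffRows(guide)
  gj <- .diffCols(guide)
  dot <- gi * e$vi + gj * e$vj
  s <- sign(dot)
  tie <- s == 0
  s[tie] <- ifelse(e$vi[tie] > 0 | (e$vi[tie] == 0 & e$vj[tie] >= 0), 1, -1)
  out <- array(0, c(dim(guide), 2L))
  out[, , 1] <- s * mag * e$vi
  out[, , 2] <- s * mag * e$vj
  out
}

#' Neighbor pair differences and means
#'
#' For every in-bounds horizontal pair (p, q = p + (d, 0)) and vertical pair
#' (p, q = p + (0, d)): the color difference u_p - u_q and mean
#' (u_p + u_q) / 2. Boundary pairs are omitted, never wrapped.
#'
#' @param img H x W x 3 numeric array.
#' @param distance positive integer pair offset (default 1).
#' @return list with arrays `dh`, `mh` (H x (W - d) x 3) and `dv`, `mv`
#'   ((H - d) x W x 3), and the `distance` used.
#' @export
pairDifferences <- function(img, distance = 1L) {
  .checkImage(img)
  d <- as.integer(distance)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (d < 1L || (d >= w && d >= h))
    stop("distance out of range for image size")
  if (d < w) {
    left <- img[, 1:(w - d), , drop = FALSE]
    right <- img[, (1 + d):w, , drop = FALSE]
    dh <- left - right; mh <- (left + right) / 2
  } else {
    dh <- mh <- array(0, c(h, 0L, 3L))
  }
  if (d < h) {
    top <- img[1:(h - d), , , drop = FALSE]
    bottom <- img[(1 + d):h, , , drop = FALSE]
    dv <- top - bottom; mv <- (top + bottom) / 2
  } else {
    dv <- mv <- array(0, c(0L, w, 3L))
  }
  list(dh = dh, mh = mh, dv = dv, mv = mv, distance = d)
}
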