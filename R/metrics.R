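# Objective evaluation: RMS local-contrast discrepancy in CIELAB, and mean
# chromatic difference in CIELAB (a, b) and proLab (atilde, btilde).

.checkSameDim <- function(ref, test) {
  .checkImage(ref, "reference image")
  .checkImage(test, "test image")
  if (!all(dim(ref) == dim(test))) stop("images must have identical dimensions")
}

.toLab <- function(img, linear) {
  if (linear) xyzToLab(linearToXYZ(img)) else srgbToLab(img)
}

# Draw neighbor coordinates for one anchor: integer pixels from a 2-D normal
# centered at (r, c), rejection-resampled to stay in bounds and differ from
# the anchor. Sampling with replacement; truncated-normal neighborhood.
.sampleNeighbors <- function(r, c, n, sigma, h, w) {
  rows <- integer(n); cols <- integer(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    k <- length(need)
    rr <- as.integer(round(stats::rnorm(k, r, sigma)))
    cc <- as.integer(round(stats::rnorm(k, c, sigma)))
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w & !(rr == r & cc == c)
    rows[need[ok]] <- rr[ok]
    cols[need[ok]] <- cc[ok]
    need <- need[!ok]
  }
  cbind(rows, cols)
}

#' RMS local-contrast difference between two images
#'
#' Both images are converted to CIELAB. Anchor pixels I lie on a regular grid
#' (`gridStep` intervals, origin at the first pixel); for each anchor i, a
#' set of neighbor pixels is drawn from a 2-D normal centered at i with
#' sigma = `sigmaFrac` * min(H, W) (out-of-bounds draws rejected and
#' resampled; the anchor itself excluded; duplicates allowed). The metric is
#' \deqn{\sqrt{\frac{1}{|I|}\sum_{i\in I}\frac{1}{|\Theta_i|}
#'   \sum_{j\in\Theta_i}\Big(\frac{\|u^{ref}_i-u^{ref}_j\|_2
#'   - \|u^{test}_i-u^{test}_j\|_2}{160}\Big)^2}.}
#' The same neighbor sets are used for both images, and the 160 normalizer
#' keeps the value within \[0, 1\] for 8-bit sRGB inputs. Identical images
#' give exactly 0 for any seed.
#'
#' @param ref,test H x W x 3 arrays of identical size: encoded sRGB by
#'   default, linear RGB when `linear = TRUE`.
#' @param spec an [RMSSamplingSpec-class]; with `neighbors = "all"` every
#'   other pixel of the image is used (deterministic, for small images).
#' @param linear interpret inputs as linear RGB instead of encoded sRGB.
#' @return a [MetricReport-class] (`metric = "RMS"`, `n` = number of
#'   anchors; `details` holds the sampling provenance).
#' @export
rmsContrast <- function(ref, test, spec = rmsSamplingSpec(), linear = FALSE) {
  .checkSameDim(ref, test)
  h <- dim(ref)[1]; w <- dim(ref)[2]
  labR <- matrix(.toLab(ref, linear), ncol = 3L)
  labT <- matrix(.toLab(test, linear), ncol = 3L)
  gridR <- seq(1L, h, by = spec@gridStep)
  gridC <- seq(1L, w, by = spec@gridStep)
  anchors <- as.matrix(expand.grid(r = gridR, c = gridC))
  sigma <- spec@sigmaFrac * min(h, w)

  pairMean <- function(i, nb) {
    ii <- (nb[, 2] - 1L) * h + nb[, 1]
    i0 <- (i[2] - 1L) * h + i[1]
    dR <- sqrt(rowSums((labR[rep(i0, length(ii)), , drop = FALSE] - labR[ii, , drop = FALSE])^2))
    dT <- sqrt(rowSums((labT[rep(i0, length(ii)), , drop = FALSE] - labT[ii, , drop = FALSE])^2))
    mean(((dR - dT) / spec@normalizer)^2)
  }

  if (spec@neighbors == "all") {
    all <- as.matrix(expand.grid(rows = seq_len(h), cols = seq_len(w)))
    perAnchor <- apply(anchors, 1L, function(i) {
      nb <- all[!(all[, 1] == i[1] & all[, 2] == i[2]), , drop = FALSE]
      pairMean(i, nb)
    })
  } else {
    # seed locally; leave the caller's RNG state untouched
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(
      if (is.null(oldSeed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", oldSeed, envir = globalenv())
    )
    set.seed(spec@seed)
    perAnchor <- apply(anchors, 1L, function(i) {
      nb <- .sampleNeighbors(i[1], i[2], spec@nNeighbors, sigma, h, w)
      pairMean(i, nb)
    })
  }
  .metricReport("RMS", sqrt(mean(perAnchor)), nrow(anchors),
                details = list(gridStep = spec@gridStep,
                               nNeighbors = spec@nNeighbors,
                               sigma = sigma, seed = spec@seed,
                               neighbors = spec@neighbors))
}

#' Mean chromatic difference in CIELAB
#'
#' Mean over all pixels of the Euclidean distance between the (a, b)
#' coordinates of the two images. CIELAB (a, b) are not invariant to
#' achromatic scaling, so this metric penalizes pure lightness changes; see
#' [cdProLab()] for the scaling-invariant variant.
#'
#' @inheritParams rmsContrast
#' @return a [MetricReport-class] (`metric = "CD_Lab"`, `n` = pixel count).
#' @export
cdLab <- function(ref, test, linear = FALSE) {
  .checkSameDim(ref, test)
  labR <- .toLab(ref, linear)
  labT <- .toLab(test, linear)
  d <- sqrt((labT[, , 2] - labR[, , 2])^2 + (labT[, , 3] - labR[, , 3])^2)
  .metricReport("CD_Lab", mean(d), length(d))
}

#' Mean chromatic difference in proLab chromaticity
#'
#' Mean over all pixels of the Euclidean distance between proLab
#' chromaticity coordinates (atilde, btilde) of the two images. Because
#' these coordinates are invariant to per-pixel positive scaling of the RGB
#' vector, any purely achromatic modification (such as the weight-mask
#' modulation of [daltonize()], before clipping) scores exactly 0.
#'
#' @inheritParams rmsContrast
#' @return a [MetricReport-class] (`metric = "CD_proLab"`).
#' @export
cdProLab <- function(ref, test, linear = FALSE) {
  .checkSameDim(ref, test)
  linR <- if (linear) ref else srgbDecode(ref)
  linT <- if (linear) test else srgbDecode(test)
  chR <- linearToProLabChromaticity(linR)
  chT <- linearToProLabChromaticity(linT)
  d <- sqrt((chT[, , 1] - chR[, , 1])^2 + (chT[, , 2] - chR[, , 2])^2)
  .metricReport("CD_proLab", mean(d), length(d))
}

#' Evaluate a set of image pairs with all objective metrics
#'
#' For each original/daltonized pair, computes the naturalness metrics
#' (CD_Lab and CD_proLab) in two regimes - "original" (trichromatic images:
#' original vs daltonized) and "simulated" (dichromat view: simulate(original)
#' vs simulate(daltonized), clipped displayable simulations) - plus the RMS
#' contrast metric with the original trichromatic image as reference:
#' `rmsNoDalt` = RMS(original, simulate(original)) and
#' `rmsDalt` = RMS(original, simulate(daltonized)). Mean and SD rows are
#' appended.
#'
#' @param originals list of H x W x 3 encoded sRGB arrays.
#' @param daltonized optional list of same-size daltonized sRGB arrays; when
#'   `NULL` only the no-daltonization contrast column is computed.
#' @param cvd `"protan"` or `"deutan"`.
#' @param spec an [RMSSamplingSpec-class] for the RMS columns.
#' @param names optional image identifiers.
#' @return data.frame with one row per image plus `mean` and `sd` rows.
#' @export
evaluateDataset <- function(originals, daltonized = NULL, cvd,
                            spec = rmsSamplingSpec(), names = NULL) {
  if (!is.list(originals)) originals <- list(originals)
  n <- length(originals)
  if (!is.null(daltonized)) {
    if (!is.list(daltonized)) daltonized <- list(daltonized)
    if (length(daltonized) != n)
      stop("originals and daltonized must have the same length")
  }
  if (is.null(names)) names <- as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    org <- originals[[i]]
    simOrg <- simulateSRGB(org, cvd)
    out <- list(image = names[i],
                rmsNoDalt = metricValue(rmsContrast(org, simOrg, spec)))
    if (!is.null(daltonized)) {
      dal <- daltonized[[i]]
      simDal <- simulateSRGB(dal, cvd)
      out$rmsDalt <- metricValue(rmsContrast(org, simDal, spec))
      out$cdLabOriginal <- metricValue(cdLab(org, dal))
      out$cdLabSimulated <- metricValue(cdLab(simOrg, simDal))
      out$cdProLabOriginal <- metricValue(cdProLab(org, dal))
      out$cdProLabSimulated <- metricValue(cdProLab(simOrg, simDal))
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1))
  summ <- rbind(
    data.frame(image = "mean", t(colMeans(tab[, num, drop = FALSE]))),
    data.frame(image = "sd", t(apply(tab[, num, drop = FALSE], 2L, stats::sd)))
  )
  rbind(tab, summ)
}
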