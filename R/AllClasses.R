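#' @import methods
NULL

#' Dichromacy simulation matrix
#'
#' A 3x3 linear operator acting on linear-RGB column vectors that projects
#' trichromatic colors onto the color plane visible to a protanope or
#' deuteranope. Valid matrices are idempotent rank-2 projections that fix the
#' gray axis (every row sums to 1), so black, white, and all grays survive
#' simulation unchanged.
#'
#' @slot type character, `"protan"` or `"deutan"`.
#' @slot M 3x3 numeric matrix acting on linear RGB.
#'
#' @seealso [simulationMatrix()], [simulateLinear()]
#' @export
setClass("CVDMatrix",
  representation(type = "character", M = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@M), c(3L, 3L)))
      msg <- c(msg, "M must be a 3x3 matrix")
    if (!object@type %in% c("protan", "deutan"))
      msg <- c(msg, "type must be 'protan' or 'deutan'")
    if (length(msg) == 0L) {
      if (max(abs(rowSums(object@M) - 1)) > 1e-9)
        msg <- c(msg, "rows of M must sum to 1 (white must be a fixed point)")
      if (max(abs(object@M %*% object@M - object@M)) > 1e-9)
        msg <- c(msg, "M must be idempotent (a projection)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn CVDMatrix-class display the matrix and its type
#' @param object a `CVDMatrix`
#' @export
setMethod("show", "CVDMatrix", function(object) {
  cat(sprintf("CVDMatrix (%s), linear-RGB projection:\n", object@type))
  print(object@M)
  invisible(object)
})

#' @describeIn CVDMatrix-class extract the raw 3x3 matrix
#' @param x a `CVDMatrix`
#' @param ... ignored
#' @export
setMethod("as.matrix", "CVDMatrix", function(x, ...) x@M)

#' @describeIn CVDMatrix-class the CVD type of the matrix
#' @export
setGeneric("cvdType", function(x) standardGeneric("cvdType"))

#' @rdname CVDMatrix-class
#' @export
setMethod("cvdType", "CVDMatrix", function(x) x@type)

#' Daltonization parameters
#'
#' Bundles the tunables of the achromatic daltonization pipeline. The defaults
#' are the operating point used throughout the package: regularization
#' `epsilon = 0.01` shared by the pairwise objective and the mask
#' reconstruction, assumed local mean mask value `wbar = 1` (the
#' no-modification baseline), `iters = 10000` Adam iterations with step
#' `0.01`, tone-map quantile `0.98`, and nearest-neighbor pairs
#' (`pairDistance = 1`).
#'
#' @slot epsilon positive regularization constant of the contrast objective.
#' @slot wbar assumed mean mask value of a neighbor pair (> 0).
#' @slot iters optimizer iteration count (>= 1).
#' @slot step optimizer step size (> 0).
#' @slot seed integer seed, reserved for stochastic optimizer variants; the
#'   default pipeline is fully deterministic.
#' @slot tonemapQuantile quantile in (0, 1] used by [toneMap()].
#' @slot pairDistance positive integer neighbor offset; distances > 1 are
#'   experimental and can introduce ridge artifacts.
#'
#' @seealso [daltonizationConfig()], [daltonize()]
#' @export
setClass("DaltonizationConfig",
  representation(
    epsilon = "numeric", wbar = "numeric", iters = "integer",
    step = "numeric", seed = "integer", tonemapQuantile = "numeric",
    pairDistance = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
    if (object@wbar <= 0) msg <- c(msg, "wbar must be > 0")
    if (object@iters < 1L) msg <- c(msg, "iters must be >= 1")
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (object@tonemapQuantile <= 0 || object@tonemapQuantile > 1)
      msg <- c(msg, "tonemapQuantile must be in (0, 1]")
    if (object@pairDistance < 1L) msg <- c(msg, "pairDistance must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a [DaltonizationConfig-class]
#'
#' @param epsilon regularization constant (default 0.01).
#' @param wbar assumed pairwise mean mask value (default 1).
#' @param iters optimizer iterations (default 10000).
#' @param step optimizer step size (default 0.01).
#' @param seed integer seed (default 1); unused by the deterministic default
#'   optimizer, kept for reproducibility bookkeeping.
#' @param tonemapQuantile tone-mapping quantile (default 0.98).
#' @param pairDistance neighbor-pair offset in pixels (default 1).
#' @return a validated `DaltonizationConfig`.
#' @examples
#' cfg <- daltonizationConfig(iters = 500)
#' cfg
#' @export
daltonizationConfig <- function(epsilon = 0.01, wbar = 1, iters = 10000L,
                                step = 0.01, seed = 1L,
                                tonemapQuantile = 0.98, pairDistance = 1L) {
  new("DaltonizationConfig",
    epsilon = as.numeric(epsilon), wbar = as.numeric(wbar),
    iters = as.integer(iters), step = as.numeric(step),
    seed = as.integer(seed), tonemapQuantile = as.numeric(tonemapQuantile),
    pairDistance = as.integer(pairDistance)
  )
}

#' @describeIn DaltonizationConfig-class display the configuration
#' @param object a `DaltonizationConfig`
#' @export
setMethod("show", "DaltonizationConfig", function(object) {
  cat("DaltonizationConfig:\n")
  cat(sprintf("  epsilon = %g, wbar = %g\n", object@epsilon, object@wbar))
  cat(sprintf("  optimizer: %d iterations, step %g\n", object@iters, object@step))
  cat(sprintf("  tone-map quantile = %g, pair distance = %d\n",
              object@tonemapQuantile, object@pairDistance))
  invisible(object)
})

#' Sampling scheme of the RMS local-contrast metric
#'
#' The RMS metric compares pairwise CIELAB distances between a reference and a
#' test image over a regular grid of anchor pixels, each paired with neighbor
#' pixels drawn from an isotropic 2-D normal distribution. Defaults follow the
#' evaluation protocol used throughout the package: 10-pixel grid, 1000
#' neighbors per anchor, sigma equal to 25% of the linear image size
#' (min(H, W)), and the 160 normalizer that keeps values within [0, 1].
#'
#' @slot gridStep grid interval in pixels.
#' @slot nNeighbors neighbors sampled per anchor pixel.
#' @slot sigmaFrac sigma as a fraction of min(H, W).
#' @slot normalizer denominator constant (160).
#' @slot seed integer seed for neighbor sampling.
#' @slot neighbors `"gaussian"` (the evaluation protocol) or `"all"` (every
#'   other pixel, exhaustive; intended for small images and validation).
#'
#' @seealso [rmsSamplingSpec()], [rmsContrast()]
#' @export
setClass("RMSSamplingSpec",
  representation(
    gridStep = "integer", nNeighbors = "integer", sigmaFrac = "numeric",
    normalizer = "numeric", seed = "integer", neighbors = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (object@gridStep < 1L) msg <- c(msg, "gridStep must be >= 1")
    if (object@nNeighbors < 1L) msg <- c(msg, "nNeighbors must be >= 1")
    if (object@sigmaFrac <= 0) msg <- c(msg, "sigmaFrac must be > 0")
    if (object@normalizer <= 0) msg <- c(msg, "normalizer must be > 0")
    if (!object@neighbors %in% c("gaussian", "all"))
      msg <- c(msg, "neighbors must be 'gaussian' or 'all'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an [RMSSamplingSpec-class]
#'
#' @param gridStep anchor-grid interval in pixels (default 10).
#' @param nNeighbors neighbors per anchor (default 1000).
#' @param sigmaFrac sigma of the neighbor distribution as a fraction of
#'   min(H, W) (default 0.25).
#' @param normalizer scale constant in the denominator (default 160).
#' @param seed sampling seed (default 1).
#' @param neighbors `"gaussian"` or `"all"` (exhaustive).
#' @return a validated `RMSSamplingSpec`.
#' @export
rmsSamplingSpec <- function(gridStep = 10L, nNeighbors = 1000L,
                            sigmaFrac = 0.25, normalizer = 160,
                            seed = 1L, neighbors = "gaussian") {
  new("RMSSamplingSpec",
    gridStep = as.integer(gridStep), nNeighbors = as.integer(nNeighbors),
    sigmaFrac = as.numeric(sigmaFrac), normalizer = as.numeric(normalizer),
    seed = as.integer(seed), neighbors = neighbors
  )
}

#' @describeIn RMSSamplingSpec-class display the sampling scheme
#' @param object an `RMSSamplingSpec`
#' @export
setMethod("show", "RMSSamplingSpec", function(object) {
  cat(sprintf(
    "RMSSamplingSpec: grid %d px, %s neighbors, sigma = %g * min(H,W), /%g, seed %d\n",
    object@gridStep,
    if (object@neighbors == "all") "all" else sprintf("%d gaussian", object@nNeighbors),
    object@sigmaFrac, object@normalizer, object@seed
  ))
  invisible(object)
})

#' Result of an objective image-quality metric
#'
#' Carries the scalar metric value together with its provenance: which metric,
#' how many pixels or samples entered the average, and the sampling parameters
#' where the metric is stochastic.
#'
#' @slot metric metric name, e.g. `"RMS"`, `"CD_Lab"`, `"CD_proLab"`.
#' @slot value non-negative scalar.
#' @slot n number of pixels (CD metrics) or anchor pixels (RMS).
#' @slot details list of provenance fields (sampling spec, seed, ...).
#'
#' @export
setClass("MetricReport",
  representation(metric = "character", value = "numeric", n = "integer",
                 details = "list"),
  validity = function(object) {
    if (!is.finite(object@value) || object@value < -1e-12)
      "value must be finite and non-negative" else TRUE
  }
)

#' @describeIn MetricReport-class display the metric value
#' @param object a `MetricReport`
#' @export
setMethod("show", "MetricReport", function(object) {
  cat(sprintf("%s = %.6g  (n = %d)\n", object@metric, object@value, object@n))
  invisible(object)
})

#' @describeIn MetricReport-class numeric value of a metric report
#' @export
setGeneric("metricValue", function(x) standardGeneric("metricValue"))

#' @rdname MetricReport-class
#' @param x a `MetricReport`
#' @export
setMethod("metricValue", "MetricReport", function(x) x@value)

.metricReport <- function(metric, value, n, details = list()) {
  new("MetricReport", metric = metric, value = as.numeric(value),
      n = as.integer(n), details = details)
}
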