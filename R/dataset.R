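# Benchmark-dataset handling: a manifest-driven loader and a convenience
# runner that reproduces the layout of published daltonization evaluation
# tables (per-image and mean +/- SD naturalness and contrast rows).

#' Load an evaluation dataset from a manifest
#'
#' The manifest is a JSON file of the form
#' \preformatted{
#' {"images": [
#'   {"name": "1", "original": "orig/1.png",
#'    "daltonized": {"protan": "dalt/protan/1.png",
#'                   "deutan": "dalt/deutan/1.png"}},
#'   ...
#' ]}
#' }
#' with paths relative to the manifest location. The `daltonized` entries are
#' optional; when absent only no-daltonization contrast rows can be computed.
#' A benchmark distribution (e.g. a downloaded evaluation image set) is used
#' by arranging its files into this layout.
#'
#' @param manifest path to the manifest JSON file.
#' @param cvd CVD type whose daltonized images to load (`"protan"` or
#'   `"deutan"`), or `NULL` to load originals only.
#' @return list with `originals` (list of sRGB arrays), `daltonized` (list or
#'   `NULL`), and `names`.
#' @export
loadDatasetManifest <- function(manifest, cvd = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to read manifests")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  root <- dirname(normalizePath(manifest))
  m <- jsonlite::read_json(manifest)
  entries <- m$images
  if (is.null(entries)) stop("manifest has no 'images' field")
  nm <- vapply(entries, function(e) as.character(e$name), character(1))
  originals <- lapply(entries, function(e)
    readImagePNG(file.path(root, e$original)))
  daltonized <- NULL
  if (!is.null(cvd)) {
    paths <- lapply(entries, function(e) e$daltonized[[cvd]])
    if (!any(vapply(paths, is.null, logical(1))))
      daltonized <- lapply(paths, function(p) readImagePNG(file.path(root, p)))
  }
  list(originals = originals, daltonized = daltonized, names = nm)
}

#' Daltonize and evaluate a whole dataset
#'
#' Runs [daltonize()] on every original image and evaluates it with
#' [evaluateDataset()], producing the per-image and mean/SD table for one
#' CVD type.
#'
#' @param originals list of encoded sRGB arrays.
#' @param cvd `"protan"` or `"deutan"`.
#' @param cfg a [DaltonizationConfig-class].
#' @param spec an [RMSSamplingSpec-class].
#' @param names optional image identifiers.
#' @return data.frame as returned by [evaluateDataset()].
#' @export
runDatasetEvaluation <- function(originals, cvd,
                                 cfg = daltonizationConfig(),
                                 spec = rmsSamplingSpec(), names = NULL) {
  daltonized <- lapply(originals, daltonize, cvd = cvd, cfg = cfg)
  evaluateDataset(originals, daltonized, cvd, spec, names)
}

#' Default local location of the evaluation dataset
#'
#' The dataset of 10 benchmark photographs used for table reproduction is an
#' optional external input (a one-time download). This helper returns the
#' directory the package looks in: the `daltonize.dataset.dir` option if
#' set, otherwise `~/daltonization-dataset`. The directory must contain a
#' `manifest.json` as described in [loadDatasetManifest()].
#'
#' @return character path (the directory need not exist).
#' @export
datasetDirectory <- function() {
  getOption("daltonize.dataset.dir",
            path.expand("~/daltonization-dataset"))
}
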