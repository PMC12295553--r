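# Shared fixture builders. All fixtures are generated in code; seeds are
# fixed so every test run sees identical inputs.

randomSRGB <- function(h, w, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * 3L), c(h, w, 3L))
}

graySRGB <- function(h, w, seed = 2L) {
  set.seed(seed)
  g <- matrix(runif(h * w), h, w)
  array(rep(g, 3L), c(h, w, 3L))
}

# small, fast configuration for unit tests (full-scale runs live in
# test-acceptance.R)
testConfig <- function(...) daltonizationConfig(iters = 500L, ...)

smallRMSSpec <- function(seed = 1L, ...) {
  rmsSamplingSpec(gridStep = 4L, nNeighbors = 200L, seed = seed, ...)
}
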