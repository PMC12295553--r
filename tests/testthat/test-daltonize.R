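# Independent quadratic-root oracle: expand the pairwise contrast equation
# and solve it with polyroot, no shared code with the package path.
oracleRoots <- function(up, uq, M, wbar) {
  du <- up - uq; um <- (up + uq) / 2
  a <- sum((M %*% um)^2)
  b <- 2 * wbar * sum((M %*% um) * (M %*% du))
  cc <- wbar^2 * sum((M %*% du)^2) - sum(du^2)
  sort(Re(polyroot(c(cc, b, a))))
}
oracleResidual <- function(dw, up, uq, M, wbar) {
  du <- up - uq; um <- (up + uq) / 2
  sum((dw * (M %*% um) + wbar * (M %*% du))^2) - sum(du^2)
}

test_that("gray pair: roots {0, -0.8}, ascending guide picks 0", {
  up <- c(0.6, 0.6, 0.6); uq <- c(0.4, 0.4, 0.4)
  M <- as.matrix(simulationMatrix("protan"))
  expect_equal(oracleRoots(up, uq, M, 1), c(-0.8, 0), tolerance = 1e-12)
  dw <- solvePairQuadratic(up, uq, "protan", wbar = 1, guideSign = 1L)
  expect_equal(dw, 0, tolerance = 1e-12)
  expect_lt(abs(oracleResidual(dw, up, uq, M, 1)), 1e-12)
})

test_that("identical pixels give zero weight difference for any sign", {
  up <- c(0.2, 0.5, 0.7)
  for (s in c(-1L, 0L, 1L))
    expect_equal(solvePairQuadratic(up, up, "deutan", guideSign = s), 0)
})

test_that("confusion pairs need a nonzero weight step and the residual vanishes at it", {
  for (cvd in c("protan", "deutan")) {
    M <- as.matrix(simulationMatrix(cvd))
    n <- kernelDirection(cvd)
    set.seed(31)
    for (k in 1:25) {
      base <- runif(3, 0.3, 0.6)
      t <- runif(1, 0.05, 0.25)
      up <- base + t * n; uq <- base - t * n
      if (any(c(up, uq) < 0) || any(c(up, uq) > 1)) next
      for (s in c(-1L, 1L)) {
        dw <- solvePairQuadratic(up, uq, cvd, wbar = 1, guideSign = s)
        expect_gt(abs(dw), 0)
        expect_lt(abs(oracleResidual(dw, up, uq, M, 1)), 1e-10)
        # the sign rule picks the extreme root of the oracle pair
        r <- oracleRoots(up, uq, M, 1)
        expect_equal(dw, if (s > 0) r[2] else r[1], tolerance = 1e-10)
      }
      # tie: a root of minimal magnitude (confusion pairs have b = 0, so the
      # roots are +/- r and either is minimal)
      dw0 <- solvePairQuadratic(up, uq, cvd, wbar = 1, guideSign = 0L)
      r <- oracleRoots(up, uq, M, 1)
      expect_equal(abs(dw0), min(abs(r)), tolerance = 1e-10)
    }
  }
})

test_that("degenerate quadratics fall back gracefully", {
  # both pixels black: a = 0 -> 0
  expect_equal(solvePairQuadratic(c(0, 0, 0), c(0, 0, 0), "protan"), 0)
  # unreachable contrast (negative discriminant) -> vertex -b/(2a);
  # construct one: tiny simulated pair signal vs large original contrast
  up <- c(0.9, 0.05, 0.5); uq <- c(0.05, 0.9, 0.5)  # near-confusion, deutan-ish
  M <- as.matrix(simulationMatrix("protan"))
  du <- up - uq; um <- (up + uq) / 2
  a <- sum((M %*% um)^2); b <- 2 * sum((M %*% um) * (M %*% du))
  cc <- sum((M %*% du)^2) - sum(du^2)
  if (b^2 - 4 * a * cc < 0) {
    dw <- solvePairQuadratic(up, uq, "protan", guideSign = 1L)
    expect_equal(dw, -b / (2 * a), tolerance = 1e-12)
  } else succeed("pair had real roots; vertex branch covered elsewhere")
  expect_error(solvePairQuadratic(c(NA, 0, 0), c(0, 0, 0), "protan"), "finite")
})

test_that("delta field is zero on grayscale and near-zero on blue-yellow images", {
  g <- srgbDecode(graySRGB(8, 8))
  df <- buildDeltaField(g, "protan", testConfig())
  expect_equal(max(abs(df$dwH)), 0, tolerance = 1e-9)
  expect_equal(max(abs(df$dwV)), 0, tolerance = 1e-9)

  by <- srgbDecode(makeControlImage("blue-yellow", size = c(8L, 8L)))
  df <- buildDeltaField(by, "deutan", testConfig())
  # blue-yellow contrast survives simulation: w = 1 is already consistent
  expect_lt(max(abs(df$dwH)), 0.02)
  expect_lt(max(abs(df$dwV)), 0.02)
})

test_that("delta field commutes with image transposition", {
  img <- srgbDecode(randomSRGB(7, 7, seed = 33))
  timg <- aperm(img, c(2, 1, 3))
  df <- buildDeltaField(img, "protan", testConfig())
  tdf <- buildDeltaField(timg, "protan", testConfig())
  expect_equal(tdf$dwH, t(df$dwV))
  expect_equal(tdf$dwV, t(df$dwH))
})

test_that("mask reconstruction: exact at zero deltas, recovers consistent 1-D chains", {
  # zero deltas: w stays exactly 1 (zero gradient at the initializer)
  deltas <- list(dwH = matrix(0, 4, 3), dwV = matrix(0, 3, 4), distance = 1L)
  w <- reconstructWeights(deltas, testConfig())
  expect_equal(unclass(w), matrix(1, 4, 4), ignore_attr = TRUE)

  # 1 x N chain with deltas generated from a known zero-mean mask
  set.seed(41)
  wTrue <- cumsum(rnorm(30, sd = 0.05))
  wTrue <- wTrue - mean(wTrue) + 1
  dw <- wTrue[-length(wTrue)] - wTrue[-1]
  deltas <- list(dwH = matrix(dw, 1), dwV = matrix(0, 0, 30), distance = 1L)
  cfg <- daltonizationConfig(iters = 5000L)
  wRec <- reconstructWeights(deltas, cfg, size = c(1L, 30L))
  expect_lt(max(abs(as.vector(wRec) - wTrue)), 1e-3)
})

test_that("mask reconstruction is antisymmetric in the deltas and non-increasing", {
  set.seed(42)
  deltas <- list(dwH = matrix(rnorm(12, sd = 0.1), 4, 3),
                 dwV = matrix(rnorm(12, sd = 0.1), 3, 4), distance = 1L)
  cfg <- daltonizationConfig(iters = 3000L)
  w1 <- reconstructWeights(deltas, cfg)
  w2 <- reconstructWeights(list(dwH = -deltas$dwH, dwV = -deltas$dwV,
                                distance = 1L), cfg)
  expect_equal(unclass(w2) - 1, -(unclass(w1) - 1), tolerance = 1e-3,
               ignore_attr = TRUE)
  tr <- attr(w1, "objectiveTrace")
  expect_true(all(diff(tr) <= 0))
  # optimization helped relative to the flat mask
  expect_lte(tail(tr, 1), tr[1])
})

test_that("weight application scales channels jointly and preserves chromaticity exactly", {
  img <- srgbDecode(randomSRGB(6, 6, seed = 43))
  expect_equal(applyWeights(img, matrix(1, 6, 6)), img)
  one <- array(c(0.1, 0.2, 0.3), c(1, 1, 3))
  expect_equal(as.vector(applyWeights(one, matrix(2, 1, 1))), c(0.2, 0.4, 0.6))
  set.seed(44)
  w <- matrix(runif(36, 0.2, 2.5), 6, 6)
  weighted <- applyWeights(img, w)
  expect_equal(metricValue(cdProLab(img, weighted, linear = TRUE)), 0,
               tolerance = 1e-12)
  expect_error(applyWeights(img, matrix(1, 3, 3)), "shape")
})

test_that("tone mapping is identity in range and pins the quantile at 1 when scaling", {
  img <- srgbDecode(randomSRGB(10, 10, seed = 45))
  expect_equal(toneMap(img), img)
  big <- img * 2
  mapped <- toneMap(big, 0.98)
  v <- pmax(big[, , 1], big[, , 2], big[, , 3])
  s <- unname(quantile(v, 0.98))  # oracle: direct quantile of channel maxima
  expect_equal(mapped, pmin(big / s, 1), tolerance = 1e-12)
  expect_true(all(mapped >= 0 & mapped <= 1))
  # the scaled (pre-clip) channel maxima have their 0.98 quantile pinned at 1,
  # so about 2% of pixels saturate after clipping
  expect_equal(unname(quantile(v / s, 0.98)), 1, tolerance = 1e-12)
  vm <- pmax(mapped[, , 1], mapped[, , 2], mapped[, , 3])
  expect_lte(mean(vm >= 1 - 1e-12), 0.03)
  expect_gte(mean(vm >= 1 - 1e-12), 0.01)
})

test_that("daltonization is the identity on grayscale images and deterministic", {
  g <- graySRGB(12, 12)
  cfg <- testConfig()
  out <- daltonize(g, "protan", cfg)
  expect_equal(unclass(out), g, tolerance = 1 / 255, ignore_attr = TRUE)
  out2 <- daltonize(g, "protan", cfg)
  expect_identical(unclass(out), unclass(out2))
})

test_that("daltonization transposes with the image", {
  # the delta field transposes exactly; the optimized mask does so only up to
  # optimizer convergence (rounding noise is amplified while Adam is far from
  # the unique minimum and dies away as it converges), so run to convergence
  # and compare at a tolerance below visual/quantization relevance
  fix <- makeConfusionImage("deutan", size = c(12L, 12L), cellSize = 4L)
  cfg <- daltonizationConfig(iters = 6000L)
  out <- daltonize(fix$image, "deutan", cfg)
  outT <- daltonize(aperm(fix$image, c(2, 1, 3)), "deutan", cfg)
  expect_equal(unclass(outT), aperm(unclass(out), c(2, 1, 3)),
               tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("the exact pairwise functional decreases on confusion fixtures", {
  for (cvd in c("protan", "deutan")) {
    fix <- makeConfusionImage(cvd, size = c(24L, 24L), cellSize = 6L)
    lin <- srgbDecode(fix$image)
    cfg <- testConfig()
    out <- daltonize(fix$image, cvd, cfg)
    w <- attr(out, "weightMask")
    f0 <- evaluateFunctional(lin, lin, cvd, cfg@epsilon)
    f1 <- evaluateFunctional(lin, applyWeights(lin, w), cvd, cfg@epsilon)
    expect_lt(f1, f0)
  }
  # gray image scores exactly zero against itself
  g <- srgbDecode(graySRGB(6, 6))
  expect_equal(evaluateFunctional(g, g, "protan"), 0, tolerance = 1e-12)
  # epsilon -> Inf drives the functional to zero
  x <- srgbDecode(randomSRGB(6, 6, seed = 46))
  y <- srgbDecode(randomSRGB(6, 6, seed = 47))
  expect_lt(evaluateFunctional(x, y, "protan", epsilon = 1e6), 1e-9)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(daltonizationConfig(epsilon = 0), "epsilon")
  expect_error(daltonizationConfig(wbar = -1), "wbar")
  expect_error(daltonizationConfig(iters = 0L), "iters")
  expect_error(daltonizationConfig(tonemapQuantile = 1.2), "tonemapQuantile")
  expect_error(daltonizationConfig(pairDistance = 0L), "pairDistance")
})
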