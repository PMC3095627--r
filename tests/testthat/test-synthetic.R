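test_that("checkerboard quadrants are pure with binary concentrations", {
  basis <- syntheticBasisSet()
  scene <- generatePhantom("checkerboard", c(64, 64), basis, seed = 0)
  C <- scene@concentrations
  expect_true(all(C %in% c(0, 1)))
  expect_equal(C[10, 10, ], c(1, 0, 0, 0))     # top-left quadrant: epithelium
  expect_equal(C[10, 50, ], c(0, 1, 0, 0))
  expect_equal(C[50, 10, ], c(0, 0, 1, 0))
  expect_equal(C[50, 50, ], c(0, 0, 0, 1))
  expect_equal(sort(unique(as.vector(scene@labelMap))), 1:4)
})

test_that("phantom generation is deterministic and validates inputs", {
  basis <- syntheticBasisSet()
  a <- generatePhantom("crypts", c(48, 48), basis, seed = 9)
  b <- generatePhantom("crypts", c(48, 48), basis, seed = 9)
  expect_identical(a@labelMap, b@labelMap)
  expect_identical(a@concentrations, b@concentrations)
  c_ <- generatePhantom("crypts", c(48, 48), basis, seed = 10)
  expect_false(identical(a@labelMap, c_@labelMap))
  expect_error(generatePhantom("spiral", c(48, 48), basis),
               "crypts, villi, peyer, lesion, checkerboard")
  expect_error(generatePhantom("crypts", c(16, 16), basis), "32")
})

test_that("crypt phantoms keep the epithelium fraction in a plausible band", {
  basis <- syntheticBasisSet()
  for (s in 0:9) {
    scene <- generatePhantom("crypts", c(64, 64), basis, seed = s)
    frac <- mean(scene@labelMap == 1)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.6)
  }
})

test_that("all presets produce valid scenes with bounded mixing zones", {
  basis <- syntheticBasisSet()
  for (g in c("villi", "peyer", "lesion")) {
    scene <- generatePhantom(g, c(48, 48), basis, seed = 1)
    expect_s4_class(scene, "PhantomScene")
    expect_true(validObject(scene))
    # mixing exists but most assigned pixels remain pure
    Cm <- matrix(scene@concentrations, ncol = 4)
    am <- max.col(Cm, "first")
    mx <- Cm[cbind(seq_len(nrow(Cm)), am)]
    assigned <- mx > 0
    pure <- assigned & (rowSums(Cm) - mx) <= 1e-9 * pmax(mx, 1)
    expect_gt(mean(pure[assigned]), 0.5)
  }
})

test_that("the forward model is linear and embeds the generation metadata", {
  basis <- syntheticBasisSet()
  # single pure pixel at unit concentration under a flat envelope
  C <- array(0, c(32, 32, 4)); C[5, 5, 3] <- 1
  lab <- matrix(0L, 32, 32); lab[5, 5] <- 3L
  scene <- new("PhantomScene", labelMap = lab, concentrations = C,
               labels = componentLabels(basis), geometry = "checkerboard",
               seed = 0L)
  st <- forwardSimulate(scene, basis)
  expect_equal(pixelSpectrum(st, 5, 5),
               basisValues(basisSpectrum(basis, "collagen")),
               ignore_attr = TRUE)
  expect_true(all(pixelSpectrum(st, 1, 1) == 0))
  # doubling concentrations doubles the noiseless stack
  scene2 <- new("PhantomScene", labelMap = lab, concentrations = 2 * C,
                labels = componentLabels(basis), geometry = "checkerboard",
                seed = 0L)
  st2 <- forwardSimulate(scene2, basis)
  expect_equal(stackData(st2), 2 * stackData(st))
  expect_identical(stackMeta(st)$phantom$geometry, "checkerboard")
})

test_that("Poisson noise follows shot-noise scaling at high counts", {
  basis <- syntheticBasisSet()
  scene <- generatePhantom("checkerboard", c(48, 48), basis, seed = 0)
  clean <- forwardSimulate(scene, basis)
  noisy <- forwardSimulate(scene, basis,
                           noise = noiseModel("poisson", 10000), seed = 1)
  scale <- stackMeta(noisy)$count_scale
  mu <- stackData(clean) * scale
  bright <- mu > 1000
  relDev <- (stackData(noisy)[bright] - mu[bright]) / mu[bright]
  pooled <- sd(relDev * sqrt(mu[bright]))   # should be ~1 for Poisson
  expect_gt(pooled, 0.8)
  expect_lt(pooled, 1.2)
  # deterministic given the seed
  noisy2 <- forwardSimulate(scene, basis,
                            noise = noiseModel("poisson", 10000), seed = 1)
  expect_identical(stackData(noisy), stackData(noisy2))
})

test_that("recovery metrics are gauge-invariant and detect permutations", {
  basis <- syntheticBasisSet()
  scene <- generatePhantom("crypts", c(64, 64), basis, seed = 0)
  ident <- new("CoefficientMaps", coeffs = scene@concentrations,
               labels = scene@labels, scaled = FALSE, maxValues = numeric(0))
  r1 <- recoveryReport(scene, ident)
  expect_true(all(r1$perComponent$pearson_r == 1))
  expect_true(all(r1$perComponent$rmse == 0))
  expect_equal(r1$pooled$argmax_accuracy, 1)
  # one global scalar per component is gauged away
  tripled <- new("CoefficientMaps", coeffs = 3 * scene@concentrations,
                 labels = scene@labels, scaled = FALSE, maxValues = numeric(0))
  r3 <- recoveryReport(scene, tripled)
  expect_true(all(r3$perComponent$pearson_r == 1))
  expect_lt(max(r3$perComponent$rmse), 1e-12)
  # swapping two components is caught by the per-component correlation
  perm <- scene@concentrations[, , c(2, 1, 3, 4)]
  swapped <- new("CoefficientMaps", coeffs = perm, labels = scene@labels,
                 scaled = FALSE, maxValues = numeric(0))
  rs <- recoveryReport(scene, swapped)
  expect_lt(rs$perComponent$pearson_r[1], 0.5)
  badLabels <- new("CoefficientMaps", coeffs = scene@concentrations,
                   labels = c("a", "b", "c", "d"), scaled = FALSE,
                   maxValues = numeric(0))
  expect_error(recoveryReport(scene, badLabels), "labels differ")
})

test_that("recovery error decreases with photon budget", {
  basis <- syntheticBasisSet(normalized = TRUE)
  levels <- c(10, 100, 1000, 10000)
  rmse <- matrix(0, 3, length(levels))
  for (si in 1:3) {
    scene <- generatePhantom("crypts", c(48, 48), basis, seed = si - 1)
    for (li in seq_along(levels)) {
      st <- forwardSimulate(scene, basis,
                            noise = noiseModel("poisson", levels[li]),
                            seed = si - 1)
      fit <- unmixStack(st, basis)
      rmse[si, li] <- recoveryReport(scene, fit$maps)$pooled$rmse
    }
  }
  pooled <- colMeans(rmse)
  # non-increasing in peak counts, allowing one inversion at the two
  # highest levels where the error floor is reached
  expect_true(pooled[2] <= pooled[1])
  expect_true(pooled[3] <= pooled[2])
  expect_true(pooled[4] <= pooled[3] * 1.05)
})

test_that("the parametric envelope is positive, unit-mean and power-sensitive", {
  wl <- defaultExcitationAxis()
  k <- parametricEnvelope(wl)
  expect_true(all(k > 0))
  expect_equal(mean(k), 1)
  # wavelength-dependent power reshapes the envelope quadratically
  P <- seq(1, 3, length.out = length(wl))
  k2 <- parametricEnvelope(wl, power_mW = P)
  expect_gt(k2[length(wl)] / k2[1], (P[length(wl)] / P[1])^2 * 0.5)
  expect_error(parametricEnvelope(wl, power_mW = -1), "positive")
})
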