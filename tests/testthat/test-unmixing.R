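test_that("the design matrix concatenates band spectra in component order", {
  basis <- syntheticBasisSet(normalized = TRUE)
  A <- buildDesignMatrix(basis, UnmixConfig())
  expect_equal(dim(A), c(43L * 2L, 4L))
  expect_identical(colnames(A), componentLabels(basis))
  sp <- basisSpectrum(basis, "collagen")
  expect_equal(A[, "collagen"],
               c(basisValues(sp)[, 1], basisValues(sp)[, 2]),
               ignore_attr = TRUE)
  # single band, single component: the column is that spectrum
  one <- BasisSet(list(basisSpectrum(basis, "epithelium")))
  A1 <- buildDesignMatrix(one, UnmixConfig(bandsUsed = "blue",
                                           components = "epithelium"))
  expect_equal(drop(A1), basisValues(basisSpectrum(basis, "epithelium"))[, 1],
               ignore_attr = TRUE)
  # permuting component order permutes columns identically
  Ap <- buildDesignMatrix(basis, UnmixConfig(components = rev(componentLabels(basis))))
  expect_equal(Ap, A[, rev(colnames(A))], ignore_attr = TRUE)
  expect_identical(colnames(Ap), rev(colnames(A)))
  # unnormalized basis is refused with a pointer to normalizeBasis
  expect_error(buildDesignMatrix(syntheticBasisSet(normalized = FALSE)),
               "normalizeBasis")
})

test_that("an exact in-model mixture is recovered with zero residual", {
  basis <- syntheticBasisSet(normalized = TRUE)
  wl <- wavelengths(basis)
  k <- 4; nr <- 6; nc <- 5
  set.seed(21)
  truthA <- array(runif(nr * nc * k), c(nr, nc, k))
  B <- lapply(basis@spectra, basisValues)
  d <- array(0, c(nr, nc, length(wl), 3))
  for (j in 1:k) for (i in seq_along(wl)) for (b in 1:3)
    d[, , i, b] <- d[, , i, b] + truthA[, , j] * B[[j]][i, b]
  d[2, 2, , ] <- 0                       # an all-zero pixel
  truthA[2, 2, ] <- 0
  st <- HyperStack(d, wavelengths = wl)
  fit <- unmixStack(st, basis)
  expect_lt(max(abs(fit$maps@coeffs - truthA)), 1e-8)
  expect_lt(max(residualValues(fit$residual)), 1e-16)
  expect_equal(residualValues(fit$residual)[2, 2], 0)
  expect_equal(fit$maps@coeffs[2, 2, ], rep(0, k))
})

test_that("unmixing is linear in the stack intensity", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("checkerboard", c(32, 32), basis, seed = 2)
  st <- forwardSimulate(scene, basis)
  st3 <- HyperStack(stackData(st) * 3, wavelengths = wavelengths(st),
                    bands = emissionBands(st))
  f1 <- unmixStack(st, basis)
  f3 <- unmixStack(st3, basis)
  expect_equal(f3$maps@coeffs, 3 * f1$maps@coeffs, tolerance = 1e-10)
})

test_that("pure-component phantom pixels take the right argmax label", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("checkerboard", c(64, 64), basis, seed = 0)
  st <- forwardSimulate(scene, basis)
  fit <- unmixStack(st, basis)
  rep_ <- recoveryReport(scene, fit$maps)
  expect_equal(rep_$pooled$argmax_accuracy, 1)
})

test_that("an out-of-model component strictly increases total residual", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("checkerboard", c(32, 32), basis, seed = 1)
  st <- forwardSimulate(scene, basis)
  base <- sum(residualValues(unmixStack(st, basis)$residual))
  wl <- wavelengths(basis)
  intruder <- exp(-((wl - 860) / 25)^2)    # narrow feature none of the bases has
  d <- stackData(st)
  for (i in seq_along(wl)) d[, , i, 1] <- d[, , i, 1] + 0.3 * intruder[i]
  st2 <- HyperStack(d, wavelengths = wl, bands = emissionBands(st))
  withMore <- sum(residualValues(unmixStack(st2, basis)$residual))
  expect_gt(withMore, base)
})

test_that("display scaling fixes the reference max at 1 and preserves ratios", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("crypts", c(48, 48), basis, seed = 4)
  st <- forwardSimulate(scene, basis)
  fit <- unmixStack(st, basis)
  scaled <- scaleCoefficientMaps(fit$maps)
  expect_equal(max(componentMap(scaled, "epithelium")), 1)
  expect_true(scaled@scaled)
  expect_equal(unname(scaled@maxValues["epithelium"]), 1)
  # idempotent
  again <- scaleCoefficientMaps(scaled)
  expect_equal(again@coeffs, scaled@coeffs)
  # ratios between components unchanged wherever defined
  r0 <- fit$maps@coeffs[, , 1] / pmax(fit$maps@coeffs[, , 3], 1e-12)
  r1 <- scaled@coeffs[, , 1] / pmax(scaled@coeffs[, , 3], 1e-12)
  keep <- fit$maps@coeffs[, , 3] > 1e-6
  expect_equal(r0[keep], r1[keep], tolerance = 1e-8)
  # all-zero reference is refused with advice
  zero <- new("CoefficientMaps",
              coeffs = array(c(rep(0, 16), runif(16)), c(4, 4, 2)),
              labels = c("epithelium", "collagen"), scaled = FALSE,
              maxValues = numeric(0))
  expect_error(scaleCoefficientMaps(zero), "displayReference")
})

test_that("calibration state mismatches between basis and stack are refused", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("checkerboard", c(32, 32), basis, seed = 0)
  st <- forwardSimulate(scene, basis)
  wl <- wavelengths(basis)
  cal <- new("CalibrationProfile", wavelengths = wl,
             envelope = testEnvelope(wl),
             channelScale = c(blue = 1, green = 1, red = 1), floor = 1e-9)
  calBasis <- BasisSet(lapply(applyCalibration(syntheticBasisSet(), cal)@spectra,
                              normalizeBasis))
  expect_error(unmixStack(st, calBasis), "calibration state mismatch")
})

test_that("free band amplitude recovers a per-pixel band multiplier", {
  basis <- syntheticBasisSet(normalized = TRUE)
  wl <- wavelengths(basis)
  B <- lapply(basis@spectra, basisValues)
  nr <- 4; nc <- 4
  set.seed(13)
  truthA <- array(runif(nr * nc * 4, 0.2, 1), c(nr, nc, 4))
  d <- array(0, c(nr, nc, length(wl), 3))
  for (j in 1:4) for (i in seq_along(wl)) for (b in 1:3)
    d[, , i, b] <- d[, , i, b] + truthA[, , j] * B[[j]][i, b]
  d[, , , 2] <- d[, , , 2] * 0.6          # attenuated green channel
  st <- HyperStack(d, wavelengths = wl)
  plain <- unmixStack(st, basis)
  free <- unmixStack(st, basis, UnmixConfig(freeBandAmplitude = TRUE))
  expect_lt(sum(residualValues(free$residual)),
            sum(residualValues(plain$residual)))
  expect_lt(max(abs(free$maps@coeffs - truthA)), 1e-3)
})

test_that("coefficient maps round-trip through the TIFF+JSON format", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("checkerboard", c(32, 32), basis, seed = 5)
  st <- forwardSimulate(scene, basis)
  fit <- unmixStack(st, basis)
  maps <- scaleCoefficientMaps(fit$maps)
  dir <- file.path(tempdir(), "mapsout")
  saveCoefficientMaps(maps, fit$residual, dir)
  back <- loadCoefficientMaps(dir)
  expect_identical(componentLabels(back$maps), componentLabels(maps))
  expect_lt(max(abs(back$maps@coeffs - maps@coeffs)), 1e-7)
  expect_lt(max(abs(residualValues(back$residual) -
                    residualValues(fit$residual))),
            1e-7 * max(1, max(residualValues(fit$residual))))
  expect_true(back$maps@scaled)
})
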