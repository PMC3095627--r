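rampStack <- function(n = 400) {
  ramp <- matrix(seq_len(n * n) - 1, n, n)
  d <- array(0, c(n, n, 1, 3))
  for (b in 1:3) d[, , 1, b] <- ramp
  HyperStack(d, wavelengths = 710)
}

test_that("the clip contract: rank-based threshold saturates the documented count", {
  st <- rampStack(400)
  img <- rgbMerge(st, 710)                      # clipFraction 0.0006
  expect_identical(unname(attr(img, "saturated")), rep(96L, 3))
  # clipFraction 0 on a ramp: linear mapping, max pixel exactly 255, none clipped
  img0 <- rgbMerge(st, 710, RenderConfig(clipFraction = 0))
  expect_identical(unname(attr(img0, "saturated")), rep(0L, 3))
  expect_identical(max(img0), 255L)
  expect_identical(min(img0), 0L)
  # constant image renders uniform full scale for any clip fraction
  cst <- tinyStack(nr = 8, nc = 8, wl = 710, fill = function(r, c, i, b) 3.3)
  expect_true(all(rgbMerge(cst, 710) == 255L))
})

test_that("merges are invariant under one global positive scaling", {
  st <- rampStack(100)
  a <- rgbMerge(st, 710)
  st@data <- st@data * 41.7
  b <- rgbMerge(st, 710)
  expect_identical(as.integer(a), as.integer(b))
})

test_that("excitation selection picks frames and rejects empty windows", {
  wl <- seq(710, 760, 5)
  st <- tinyStack(nr = 4, nc = 4, wl = wl,
                  fill = function(r, c, i, b) i * 10)
  # a 25 nm window is an unweighted mean of the frames inside it
  img <- rgbMerge(st, c(722.5, 747.5), RenderConfig(clipFraction = 0))
  expect_true(all(img == 255L))                 # constant per-frame values
  expect_error(rgbMerge(st, 1000), "outside the axis")
  expect_error(rgbMerge(st, c(761, 769)), "does not intersect")
  noRed <- tinyStack(nr = 4, nc = 4, wl = wl, nb = 2)
  expect_error(rgbMerge(noRed, 710), "red")
})

test_that("component grayscale panels carry the m.v. annotation", {
  coeffs <- array(0, c(4, 4, 3))
  coeffs[, , 1] <- matrix(runif(16), 4, 4); coeffs[1, 1, 1] <- 1
  coeffs[, , 2] <- 0.25 * coeffs[, , 1]
  maps <- new("CoefficientMaps", coeffs = coeffs,
              labels = c("epithelium", "collagen", "lymphatic"),
              scaled = TRUE, maxValues = c(epithelium = 1, collagen = 0.25,
                                           lymphatic = 0))
  g1 <- componentGrayscale(maps, "epithelium")
  expect_equal(g1$maxValue, 1)
  expect_identical(max(g1$image), 255L)
  g2 <- componentGrayscale(maps, "collagen")
  expect_equal(g2$maxValue, 0.25)
  expect_identical(max(g2$image), 255L)         # scaled to its own max
  g3 <- componentGrayscale(maps, "lymphatic")   # all-zero: black, m.v. 0
  expect_true(all(g3$image == 0L))
  expect_equal(g3$maxValue, 0)
  unscaled <- new("CoefficientMaps", coeffs = coeffs,
                  labels = maps@labels, scaled = FALSE, maxValues = numeric(0))
  expect_error(componentGrayscale(unscaled, "epithelium"),
               "scaleCoefficientMaps")
})

test_that("false-color composites tint disjoint supports without bleeding", {
  coeffs <- array(0, c(6, 6, 2))
  coeffs[1:3, , 1] <- 1; coeffs[4:6, , 2] <- 0.5
  maps <- new("CoefficientMaps", coeffs = coeffs,
              labels = c("collagen", "lymphatic"), scaled = TRUE,
              maxValues = c(collagen = 1, lymphatic = 0.5))
  img <- falseColorComposite(maps)
  expect_identical(img[1, 1, ], c(0L, 0L, 255L))     # collagen -> blue
  expect_identical(img[6, 6, ], c(0L, 255L, 0L))     # lymphatic -> green
  expect_identical(img[1, 1, 2], 0L)                 # no green in blue zone
  badCfg <- RenderConfig(colormap = list(collagen = c(0, 0, 1)))
  expect_error(falseColorComposite(maps, badCfg), "lymphatic")
})

test_that("phantom composites color pure regions by their true label", {
  basis <- syntheticBasisSet(normalized = TRUE)
  scene <- generatePhantom("crypts", c(64, 64), basis, seed = 0)
  st <- forwardSimulate(scene, basis)
  maps <- scaleCoefficientMaps(unmixStack(st, basis)$maps)
  cfg <- RenderConfig()
  img <- falseColorComposite(maps, cfg)
  cols <- vapply(componentLabels(maps), function(l) cfg$colormap[[l]],
                 numeric(3))
  # classify each pixel by nearest configured color direction
  Cm <- matrix(scene@concentrations, ncol = 4)
  am <- max.col(Cm, "first")
  mx <- Cm[cbind(seq_len(nrow(Cm)), am)]
  interior <- mx >= 0.999 & (rowSums(Cm) - mx) <= 1e-9
  px <- matrix(as.numeric(img), ncol = 3)
  sim <- px %*% cols / (sqrt(rowSums(px^2)) %o% sqrt(colSums(cols^2)) + 1e-12)
  match_ <- max.col(sim, "first") == am
  expect_gt(mean(match_[interior]), 0.99)
})
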