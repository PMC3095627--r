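test_that("pixelSpectrum returns the indexed slice and rejects out-of-bounds", {
  st <- tinyStack(fill = function(r, c, i, b) (i - 1) + 10 * (b - 1))
  m <- pixelSpectrum(st, 2, 3)
  expect_equal(dim(m), c(2L, 3L))
  for (i in 1:2) for (b in 1:3)
    expect_identical(m[i, b], (i - 1) + 10 * (b - 1))
  const <- tinyStack()
  expect_true(all(pixelSpectrum(const, 1, 1) == 7))
  expect_error(pixelSpectrum(st, -1, 1), "out of bounds")
  expect_error(pixelSpectrum(st, 1, 5), "out of bounds")
  # the return is a copy: mutating it leaves the stack untouched
  m[1, 1] <- 999
  expect_identical(stackData(st)[2, 3, 1, 1], 0)
})

test_that("save/load round-trips integer stacks exactly with the right page count", {
  st <- tinyStack(fill = function(r, c, i, b) ((r * 7 + c * 13 + i + b) %% 1000))
  f <- file.path(tempdir(), "rt.tif")
  saveHyperStack(st, f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".json")))
  expect_length(tiff::readTIFF(f, all = TRUE), 2 * 3)
  st2 <- loadHyperStack(f)
  expect_identical(stackData(st2), stackData(st))
  expect_equal(wavelengths(st2), wavelengths(st))
  expect_equal(emissionBands(st2)$name, emissionBands(st)$name)
})

test_that("float stacks round-trip within 1e-7 of the stack maximum", {
  set.seed(11)
  st <- HyperStack(array(runif(4 * 4 * 3 * 2) * 517.3, c(4, 4, 3, 2)),
                   wavelengths = c(710, 715, 720))
  f <- file.path(tempdir(), "rtf.tif")
  saveHyperStack(st, f)
  st2 <- loadHyperStack(f)
  expect_lt(max(abs(stackData(st2) - stackData(st))) / max(stackData(st)), 1e-7)
})

test_that("invalid stacks and dialect mismatches are rejected", {
  st <- tinyStack()
  bad <- st
  bad@data[1, 1, 1, 1] <- NaN
  f <- file.path(tempdir(), "bad.tif")
  unlink(c(f, paste0(f, ".json")))
  expect_error(saveHyperStack(bad, f), "finite")
  expect_false(file.exists(f))

  # 5 pages against a sidecar declaring 2 x 3
  f2 <- file.path(tempdir(), "mismatch.tif")
  tiff::writeTIFF(replicate(5, matrix(0.5, 3, 3), simplify = FALSE), f2)
  saveHyperStack(st, file.path(tempdir(), "donor.tif"))
  file.copy(paste0(file.path(tempdir(), "donor.tif"), ".json"),
            paste0(f2, ".json"), overwrite = TRUE)
  expect_error(loadHyperStack(f2), "5 pages.*6 pages")

  # unsorted sidecar wavelengths
  f3 <- file.path(tempdir(), "unsorted.tif")
  saveHyperStack(st, f3)
  sc <- jsonlite::read_json(paste0(f3, ".json"))
  sc$wavelengths_nm <- list(715, 710)
  jsonlite::write_json(sc, paste0(f3, ".json"), auto_unbox = TRUE)
  expect_error(loadHyperStack(f3), "increasing")

  # missing sidecar names the expected file
  f4 <- file.path(tempdir(), "nosidecar.tif")
  file.copy(file.path(tempdir(), "donor.tif"), f4, overwrite = TRUE)
  expect_error(loadHyperStack(f4), "nosidecar\\.tif\\.json")

  # wraparound / invalid axes at construction
  expect_error(HyperStack(array(1, c(2, 2, 2, 1)), wavelengths = c(715, 710)),
               "increasing")
  expect_error(HyperStack(array(1, c(2, 2, 2, 1)), wavelengths = c(100, 200)),
               "650")
})

test_that("negative raw values are clipped to zero with a recorded count", {
  d <- array(5, c(3, 3, 2, 2)); d[1, 1, 1, 1] <- -4; d[2, 2, 2, 2] <- -1
  expect_message(st <- HyperStack(d, wavelengths = c(710, 715)), "clipped 2")
  expect_identical(min(stackData(st)), 0)
  expect_identical(stackMeta(st)$clipped_negative, 2L)
})

test_that("permuting band order in data and metadata together is a no-op", {
  set.seed(3)
  d <- array(sample(0:99, 3 * 3 * 2 * 3, TRUE), c(3, 3, 2, 3))
  bands <- defaultEmissionBands()
  perm <- c(3L, 1L, 2L)
  st1 <- HyperStack(d, wavelengths = c(710, 715), bands = bands)
  st2 <- HyperStack(d[, , , perm], wavelengths = c(710, 715),
                    bands = bands[perm, ])
  f1 <- file.path(tempdir(), "p1.tif"); f2 <- file.path(tempdir(), "p2.tif")
  saveHyperStack(st1, f1); saveHyperStack(st2, f2)
  r1 <- loadHyperStack(f1); r2 <- loadHyperStack(f2)
  # same physical content: looking up any band by name gives the same frame
  for (nm in bands$name) {
    b1 <- match(nm, emissionBands(r1)$name)
    b2 <- match(nm, emissionBands(r2)$name)
    expect_identical(stackData(r1)[, , , b1], stackData(r2)[, , , b2])
  }
})

test_that("ROI masks come from matrices or PNG files and must be non-empty", {
  roi <- matrix(FALSE, 4, 4); roi[2, 2] <- TRUE
  expect_identical(readROIMask(roi), roi)
  p <- file.path(tempdir(), "roi.png")
  png::writePNG(matrix(c(0, 1, 0, 1), 2, 2), p)
  expect_identical(readROIMask(p), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  st <- tinyStack()
  expect_error(extractROISpectrum(st, matrix(FALSE, 4, 4), "x"), "empty")
})
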