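#' @include AllClasses.R basis.R nnls.R
NULL

#' Unmixing configuration
#'
#' Settings for pixel-by-pixel spectral unmixing. By default only the
#' blue and green emission channels enter the fit: the red channel's
#' relative amplitude varies strongly with depth and blood content
#' (hemoglobin attenuates red emission very differently from blue and
#' green), which degrades fits, so it is opt-in. The display reference
#' is the component whose coefficient map is scaled to a maximum of 1
#' (conventionally epithelium), making every other map's maximum
#' interpretable relative to the epithelial abundance.
#'
#' @param bandsUsed Band names entering the fit (default blue + green).
#' @param components Component labels to fit (default: all in the basis).
#' @param displayReference Component scaled to max 1 for display.
#' @param freeBandAmplitude If \code{TRUE}, each non-blue band gets one
#'   free positive per-pixel amplitude multiplier, estimated by
#'   alternating NNLS (an opt-in alternative that can make the red
#'   channel usable).
#' @return A list of class \code{"UnmixConfig"}.
#' @export
UnmixConfig <- function(bandsUsed = c("blue", "green"), components = NULL,
                        displayReference = "epithelium",
                        freeBandAmplitude = FALSE) {
  if (length(bandsUsed) < 1L)
    stop("bandsUsed must name at least one emission band", call. = FALSE)
  structure(list(bandsUsed = bandsUsed, components = components,
                 displayReference = displayReference,
                 freeBandAmplitude = isTRUE(freeBandAmplitude)),
            class = "UnmixConfig")
}

#' Build the unmixing design matrix
#'
#' Column j is component j's excitation spectra concatenated over the
#' used bands, in band order: an \code{[n_ex * n_bands_used] x k}
#' matrix. The basis must be blue-max normalized first (the convention
#' under which coefficients are comparable across components). A
#' condition number above 1e8 triggers a warning that equal-residual
#' solutions may not be unique.
#'
#' @param basis A normalized [BasisSet-class].
#' @param cfg An [UnmixConfig()].
#' @return Numeric matrix with column names = component labels.
#' @export
buildDesignMatrix <- function(basis, cfg = UnmixConfig()) {
  stopifnot(is(basis, "BasisSet"))
  labs <- cfg$components %||% componentLabels(basis)
  sp <- lapply(labs, function(l) basisSpectrum(basis, l))
  if (!all(vapply(sp, function(s) isTRUE(s@normalized), TRUE)))
    stop("basis spectra must be normalized before unmixing; apply normalizeBasis()",
         call. = FALSE)
  bandNames <- sp[[1L]]@bands
  bi <- match(cfg$bandsUsed, bandNames)
  if (any(is.na(bi)))
    stop("band(s) not in basis: ",
         paste(cfg$bandsUsed[is.na(bi)], collapse = ", "), call. = FALSE)
  A <- vapply(sp, function(s) as.vector(s@values[, bi, drop = FALSE]),
              numeric(nrow(sp[[1L]]@values) * length(bi)))
  A <- matrix(A, ncol = length(sp))
  colnames(A) <- labs
  kap <- kappa(A, exact = TRUE)
  if (is.finite(kap) && kap > 1e8)
    warning(sprintf("design matrix condition number %.3g > 1e8: NNLS solutions may be non-unique",
                    kap), call. = FALSE)
  A
}

# Alternating NNLS for the free-band-amplitude option: coefficients and
# per-band multipliers (blue fixed at 1, init all 1) are refit in turn
# until the residual improves by < 1e-8 (max 50 iterations).
.fitFreeBand <- function(A, bvec, segIdx, freeSeg) {
  mult <- rep(1, length(segIdx))
  prev <- Inf
  x <- numeric(ncol(A))
  for (it in seq_len(50L)) {
    Aw <- A
    for (s in seq_along(segIdx))
      if (mult[s] != 1) Aw[segIdx[[s]], ] <- A[segIdx[[s]], ] * mult[s]
    fit <- nnlsSolve(Aw, bvec)
    x <- fit$x
    for (s in seq_along(segIdx)) {
      if (!freeSeg[s]) next
      pred <- drop(A[segIdx[[s]], , drop = FALSE] %*% x)
      den <- sum(pred * pred)
      mult[s] <- if (den > 0) max(0, sum(pred * bvec[segIdx[[s]]]) / den) else 1
    }
    res <- 0
    for (s in seq_along(segIdx)) {
      pred <- mult[s] * drop(A[segIdx[[s]], , drop = FALSE] %*% x)
      res <- res + sum((bvec[segIdx[[s]]] - pred)^2)
    }
    if (prev - res < 1e-8) break
    prev <- res
  }
  list(x = x, rnorm2 = res, mult = mult)
}

#' Unmix a hyperspectral stack pixel-by-pixel
#'
#' Fits every pixel's concatenated excitation spectrum (over the used
#' emission bands) as a non-negative linear combination of the basis
#' spectra, yielding one coefficient per component per pixel plus the
#' squared Euclidean norm of the fit residual. Per-pixel fits are
#' independent and the result does not depend on execution order. The
#' basis and stack must agree in calibration state: mixing a calibrated
#' basis with an uncalibrated stack (or vice versa) is refused, since
#' the instrument envelope must cancel between the two.
#'
#' @param stack A [HyperStack-class].
#' @param basis A normalized [BasisSet-class] on the same excitation axis.
#' @param cfg An [UnmixConfig()].
#' @return List with \code{maps} (a [CoefficientMaps-class], unscaled)
#'   and \code{residual} (a [ResidualMap-class]).
#' @seealso [scaleCoefficientMaps()], [nnlsSolve()]
#' @export
unmixStack <- function(stack, basis, cfg = UnmixConfig()) {
  stopifnot(is(stack, "HyperStack"), is(basis, "BasisSet"))
  if (!isTRUE(all.equal(stack@wavelengths, wavelengths(basis))))
    stop("stack and basis do not share the same excitation axis", call. = FALSE)
  stackCal <- isTRUE(stack@meta$calibrated)
  basisCal <- isTRUE(basis@spectra[[1L]]@calibrated)
  if (stackCal != basisCal)
    stop("calibration state mismatch: stack is ",
         if (stackCal) "calibrated" else "uncalibrated", " but basis is ",
         if (basisCal) "calibrated" else "uncalibrated", call. = FALSE)
  bi <- match(cfg$bandsUsed, stack@bands$name)
  if (any(is.na(bi)))
    stop("band(s) not in stack: ",
         paste(cfg$bandsUsed[is.na(bi)], collapse = ", "), call. = FALSE)
  A <- buildDesignMatrix(basis, cfg)
  d <- dim(stack@data)
  nr <- d[1L]; nc <- d[2L]; nex <- d[3L]; nbu <- length(bi)
  npix <- nr * nc
  # M: [n_ex * n_bands_used] x n_pixels, band-major concatenation per column
  M <- aperm(stack@data[, , , bi, drop = FALSE], c(3L, 4L, 1L, 2L))
  dim(M) <- c(nex * nbu, npix)
  k <- ncol(A)
  X <- matrix(0, k, npix)
  if (cfg$freeBandAmplitude) {
    segIdx <- split(seq_len(nex * nbu), rep(seq_len(nbu), each = nex))
    freeSeg <- cfg$bandsUsed != "blue"
    rn <- numeric(npix)
    for (j in seq_len(npix)) {
      fit <- .fitFreeBand(A, M[, j], segIdx, freeSeg)
      X[, j] <- fit$x
      rn[j] <- fit$rnorm2
    }
  } else {
    G <- crossprod(A)
    aAll <- crossprod(A, M)
    for (j in seq_len(npix)) X[, j] <- .nnlsGram(G, aAll[, j])
    R <- M - A %*% X
    rn <- colSums(R * R)
  }
  coeffs <- array(t(X), c(nr, nc, k))
  maps <- new("CoefficientMaps", coeffs = coeffs, labels = colnames(A),
              scaled = FALSE, maxValues = numeric(0))
  res <- new("ResidualMap", values = matrix(rn, nr, nc))
  list(maps = maps, residual = res)
}

#' Scale coefficient maps for display
#'
#' Divides every component map by the maximum of the display-reference
#' component's map (epithelium by convention), so that reference
#' maximum becomes exactly 1 and every other map's maximum -- recorded
#' in \code{maxValues}, the "m.v." annotation of the grayscale panels
#' -- reads as abundance relative to epithelium. Ratios between
#' components at any pixel are unchanged; the operation is idempotent.
#'
#' @param maps A [CoefficientMaps-class].
#' @param cfg An [UnmixConfig()] naming the display reference.
#' @return The scaled [CoefficientMaps-class].
#' @export
scaleCoefficientMaps <- function(maps, cfg = UnmixConfig()) {
  stopifnot(is(maps, "CoefficientMaps"))
  ri <- match(cfg$displayReference, maps@labels)
  if (is.na(ri))
    stop("display reference '", cfg$displayReference,
         "' is not among the components", call. = FALSE)
  m <- max(maps@coeffs[, , ri])
  if (m <= 0)
    stop("reference component '", cfg$displayReference,
         "' map is all zero; choose a different displayReference", call. = FALSE)
  coeffs <- maps@coeffs / m
  mv <- apply(coeffs, 3L, max)
  names(mv) <- maps@labels
  initialize(maps, coeffs = coeffs, scaled = TRUE, maxValues = mv)
}

#' Save / load coefficient and residual maps
#'
#' Component maps are written as one float multi-page TIFF (one page
#' per component, in label order), the residual map as a single-page
#' TIFF, plus a JSON sidecar with labels, scaling state and max values.
#'
#' @param maps A [CoefficientMaps-class].
#' @param residual A [ResidualMap-class] or \code{NULL}.
#' @param dir Output directory (created if needed).
#' @return \code{saveCoefficientMaps}: \code{dir} invisibly;
#'   \code{loadCoefficientMaps}: list with \code{maps} and
#'   \code{residual} (NULL if absent).
#' @export
saveCoefficientMaps <- function(maps, residual = NULL, dir) {
  stopifnot(is(maps, "CoefficientMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- dim(maps@coeffs)[3L]
  mx <- max(maps@coeffs)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(k), function(i) maps@coeffs[, , i] / scale)
  tiff::writeTIFF(pages, file.path(dir, "coefficients.tif"),
                  bits.per.sample = 32L, compression = "none")
  side <- list(labels = maps@labels, scaled = maps@scaled,
               max_values = as.list(maps@maxValues), scale = scale)
  if (!is.null(residual)) {
    rv <- residual@values
    rmx <- max(rv)
    rscale <- if (rmx > 0) rmx else 1
    tiff::writeTIFF(list(rv / rscale), file.path(dir, "residual.tif"),
                    bits.per.sample = 32L, compression = "none")
    side$residual_scale <- rscale
  }
  jsonlite::write_json(side, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveCoefficientMaps
#' @export
loadCoefficientMaps <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "coefficients.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  coeffs <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) coeffs[, , i] <- pages[[i]] * side$scale
  mv <- unlist(side$max_values)
  maps <- new("CoefficientMaps", coeffs = coeffs,
              labels = as.character(side$labels),
              scaled = isTRUE(side$scaled),
              maxValues = if (is.null(mv)) numeric(0) else mv)
  res <- NULL
  rpath <- file.path(dir, "residual.tif")
  if (file.exists(rpath)) {
    rv <- tiff::readTIFF(rpath, all = TRUE)
    if (is.list(rv)) rv <- rv[[1L]]
    res <- new("ResidualMap", values = rv * side$residual_scale)
  }
  list(maps = maps, residual = res)
}
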