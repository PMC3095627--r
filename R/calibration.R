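#' @include AllClasses.R hyperstack.R
NULL

#' Measure the instrument excitation envelope from a reference scan
#'
#' The wavelength-dependent multiplicative envelope K of a two-photon
#' system (laser power, pulse width, dispersion, NA, wavelength) is
#' estimated empirically as the excitation spectrum of a homogeneous
#' FAD reference well, whose two-photon action cross section is close
#' to flat across 710--900 nm: the green-channel ROI mean at each
#' wavelength is then K times a single scalar. Envelope values at or
#' below the guard floor (\code{1e-6} of the envelope maximum) are
#' raised to the floor with a warning.
#'
#' @param fadStack [HyperStack-class] scan of the reference well.
#' @param roi ROI mask (logical matrix or PNG path) selecting well pixels.
#' @param band Emission band to read the envelope from (default "green").
#' @return A [CalibrationProfile-class] with all channel scales 1.
#' @export
measureReferenceEnvelope <- function(fadStack, roi, band = "green") {
  stopifnot(is(fadStack, "HyperStack"))
  roi <- .checkROI(roi, fadStack)
  bi <- match(band, fadStack@bands$name)
  if (is.na(bi))
    stop("band '", band, "' not present in the stack", call. = FALSE)
  nex <- length(fadStack@wavelengths)
  env <- vapply(seq_len(nex), function(i) {
    frame <- fadStack@data[, , i, bi]
    mean(frame[roi])
  }, numeric(1L))
  floor <- 1e-6 * max(env, 0)
  if (floor <= 0) floor <- .Machine$double.eps
  nlow <- sum(env <= floor)
  if (nlow > 0) {
    warning(nlow, " envelope value(s) at or below the floor (",
            signif(floor, 3), ") were raised to it", call. = FALSE)
    env[env <= floor] <- floor
  }
  cs <- rep(1, nrow(fadStack@bands))
  names(cs) <- fadStack@bands$name
  new("CalibrationProfile", wavelengths = fadStack@wavelengths,
      envelope = env, channelScale = cs, floor = floor)
}

#' Per-channel scale factors from matched-power LED readings
#'
#' With narrow-band LEDs adjusted to identical optical power inside each
#' emission channel's bandwidth, detector response differences are
#' corrected by \code{scale[b] = reading[blue] / reading[b]}; blue maps
#' to exactly 1.
#'
#' @param readings Named positive numeric vector of per-band mean
#'   intensities; must include \code{"blue"}.
#' @return Named scale-factor vector, blue first equal to 1.
#' @export
#' @examples
#' channelScaleFactors(c(blue = 10, green = 5, red = 2))
channelScaleFactors <- function(readings) {
  if (is.null(names(readings)) || !"blue" %in% names(readings))
    stop("readings must be named and include 'blue'", call. = FALSE)
  if (any(!is.finite(readings)) || any(readings <= 0))
    stop("all LED readings must be positive", call. = FALSE)
  cs <- readings[["blue"]] / readings
  cs[["blue"]] <- 1
  cs
}

#' Apply spectral calibration
#'
#' Divides each excitation spectrum by the measured envelope and applies
#' the per-band channel scales:
#' \code{out[i, b] = x[i, b] / envelope[i] * channelScale[b]}. Methods
#' exist for a plain \code{[n_ex x n_bands]} matrix, a
#' [BasisSpectrum-class] (values and std are scaled identically and the
#' \code{calibrated} flag is set), a [BasisSet-class], and a whole
#' [HyperStack-class] (which records \code{meta$calibrated = TRUE}).
#' Calibration is intended for interpretation and plotting of basis
#' signatures; unmixing consumes uncalibrated spectra by default since
#' the envelope cancels between basis and data.
#'
#' @param x Matrix, [BasisSpectrum-class], [BasisSet-class] or
#'   [HyperStack-class].
#' @param cal A [CalibrationProfile-class] on the same excitation axis.
#' @return Object of the same class as \code{x}, calibrated.
#' @export
setGeneric("applyCalibration", function(x, cal) standardGeneric("applyCalibration"))

.calMatrix <- function(m, cal, bandNames) {
  if (nrow(m) != length(cal@envelope))
    stop(sprintf("spectrum has %d wavelengths but calibration has %d",
                 nrow(m), length(cal@envelope)), call. = FALSE)
  cs <- cal@channelScale[bandNames]
  if (any(is.na(cs)))
    stop("calibration lacks channel scales for band(s): ",
         paste(bandNames[is.na(cs)], collapse = ", "), call. = FALSE)
  out <- sweep(m, 1L, cal@envelope, "/")
  out <- sweep(out, 2L, cs, "*")
  .assertFinite(out, "calibrated spectrum")
  out
}

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "matrix", function(x, cal) {
  bn <- colnames(x) %||% names(cal@channelScale)[seq_len(ncol(x))]
  .calMatrix(x, cal, bn)
})

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "BasisSpectrum", function(x, cal) {
  v <- .calMatrix(x@values, cal, x@bands)
  s <- .calMatrix(x@std, cal, x@bands)
  initialize(x, values = v, std = s, calibrated = TRUE, normalized = FALSE)
})

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "BasisSet", function(x, cal) {
  new("BasisSet", spectra = lapply(x@spectra, applyCalibration, cal = cal))
})

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "HyperStack", function(x, cal) {
  d <- dim(x@data)
  if (d[3L] != length(cal@envelope))
    stop("stack and calibration excitation axes differ in length", call. = FALSE)
  cs <- cal@channelScale[x@bands$name]
  if (any(is.na(cs)))
    stop("calibration lacks channel scales for some stack bands", call. = FALSE)
  out <- x@data
  for (i in seq_len(d[3L])) out[, , i, ] <- out[, , i, ] / cal@envelope[i]
  for (b in seq_len(d[4L])) out[, , , b] <- out[, , , b] * cs[b]
  meta <- x@meta
  meta$calibrated <- TRUE
  initialize(x, data = out, meta = meta)
})

#' Serialize / restore a calibration profile as JSON
#'
#' @param cal A [CalibrationProfile-class].
#' @param path JSON file path.
#' @return \code{saveCalibration}: \code{path} invisibly;
#'   \code{loadCalibration}: a [CalibrationProfile-class].
#' @export
saveCalibration <- function(cal, path) {
  stopifnot(is(cal, "CalibrationProfile"))
  jsonlite::write_json(
    list(wavelengths_nm = cal@wavelengths, envelope = cal@envelope,
         channel_scale = as.list(cal@channelScale), floor = cal@floor),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCalibration
#' @export
loadCalibration <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationProfile",
      wavelengths = as.numeric(sc$wavelengths_nm),
      envelope = as.numeric(sc$envelope),
      channelScale = unlist(sc$channel_scale),
      floor = as.numeric(sc$floor))
}
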