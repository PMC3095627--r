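#' @import methods
NULL

#' Default excitation axis
#'
#' The standard tuning grid of the excitation-scanning acquisition:
#' 710 to 920 nm in 5 nm increments (43 wavelengths).
#'
#' @return Numeric vector of excitation wavelengths in nm.
#' @export
#' @examples
#' length(defaultExcitationAxis())
defaultExcitationAxis <- function() seq(710, 920, by = 5)

#' Default emission bands
#'
#' The three simultaneously collected detector windows: blue (350--505 nm),
#' green (505--560 nm) and red (560--650 nm).
#'
#' @return A data.frame with columns \code{name}, \code{low_nm}, \code{high_nm}.
#' @export
defaultEmissionBands <- function() {
  data.frame(name = c("blue", "green", "red"),
             low_nm = c(350, 505, 560),
             high_nm = c(505, 560, 650),
             stringsAsFactors = FALSE)
}

.validExcitation <- function(wl) {
  if (length(wl) < 1L) return("excitation axis is empty")
  if (!all(is.finite(wl))) return("excitation wavelengths must be finite")
  if (any(diff(wl) <= 0)) return("excitation wavelengths must be strictly increasing")
  if (any(wl < 650) || any(wl > 1100))
    return("excitation wavelengths must lie within [650, 1100] nm")
  NULL
}

.validBands <- function(bands) {
  if (!is.data.frame(bands) ||
      !all(c("name", "low_nm", "high_nm") %in% names(bands)))
    return("emission bands must be a data.frame with columns name, low_nm, high_nm")
  if (nrow(bands) < 1L) return("at least one emission band is required")
  if (anyDuplicated(bands$name)) return("emission band names must be unique")
  if (any(bands$low_nm >= bands$high_nm))
    return("each emission band needs low_nm < high_nm")
  o <- order(bands$low_nm)
  lo <- bands$low_nm[o]; hi <- bands$high_nm[o]
  if (nrow(bands) > 1L && any(lo[-1L] < hi[-nrow(bands)]))
    return("emission bands must not overlap")
  NULL
}

#' HyperStack: a 4-D excitation-scanned image stack
#'
#' Central measurement container: detector counts indexed
#' \code{[row, col, excitation, band]} together with the excitation axis
#' (nm, strictly increasing) and the emission-band table. Intensities must
#' be finite and non-negative. Spatial indexing is row-major with origin
#' top-left; excitation index 1 is the shortest wavelength.
#'
#' @slot data 4-D numeric array \code{[row, col, excitation, band]}.
#' @slot wavelengths Numeric excitation wavelengths (nm).
#' @slot bands data.frame of emission bands (\code{name, low_nm, high_nm}).
#' @slot meta Free-form named list (sample id, depth, power, ...).
#'
#' @seealso [HyperStack()], [saveHyperStack()], [loadHyperStack()],
#'   [pixelSpectrum()]
#' @export
setClass("HyperStack",
         representation(data = "array", wavelengths = "numeric",
                        bands = "data.frame", meta = "list"))

setValidity("HyperStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L)
    return("data must be a 4-D array [row, col, excitation, band]")
  msg <- .validExcitation(object@wavelengths)
  if (!is.null(msg)) return(msg)
  msg <- .validBands(object@bands)
  if (!is.null(msg)) return(msg)
  if (dim(d)[3L] != length(object@wavelengths))
    return(sprintf("3rd data dimension (%d) != number of wavelengths (%d)",
                   dim(d)[3L], length(object@wavelengths)))
  if (dim(d)[4L] != nrow(object@bands))
    return(sprintf("4th data dimension (%d) != number of emission bands (%d)",
                   dim(d)[4L], nrow(object@bands)))
  if (!all(is.finite(d))) return("intensities must all be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  TRUE
})

#' BasisSpectrum: excitation--emission signature of one tissue type
#'
#' A per-tissue matrix of mean intensities over the excitation axis
#' (rows) and emission bands (columns), with an optional same-shaped
#' standard-deviation matrix and provenance counts. When
#' \code{normalized} is \code{TRUE} the maximum of the blue-band column
#' is exactly 1 (the convention under which basis sets are averaged and
#' unmixed).
#'
#' @slot label Tissue name (e.g. \code{"epithelium"}).
#' @slot values Matrix \code{[n_ex x n_bands]}, non-negative and finite.
#' @slot std Same-shape matrix of standard deviations (may be all zero).
#' @slot wavelengths Excitation axis (nm).
#' @slot bands Character vector of band names (column order of values).
#' @slot nSites,nAnimals Provenance counts.
#' @slot normalized Logical; blue-max-1 normalization applied?
#' @slot calibrated Logical; instrument envelope divided out?
#' @export
setClass("BasisSpectrum",
         representation(label = "character", values = "matrix", std = "matrix",
                        wavelengths = "numeric", bands = "character",
                        nSites = "integer", nAnimals = "integer",
                        normalized = "logical", calibrated = "logical"))

setValidity("BasisSpectrum", function(object) {
  v <- object@values
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single non-empty string")
  if (nrow(v) != length(object@wavelengths))
    return("values must have one row per excitation wavelength")
  if (ncol(v) != length(object@bands))
    return("values must have one column per emission band")
  if (!all(is.finite(v)) || any(v < 0))
    return("values must be finite and non-negative")
  if (!identical(dim(object@std), dim(v)))
    return("std must have the same shape as values")
  msg <- .validExcitation(object@wavelengths)
  if (!is.null(msg)) return(msg)
  if (isTRUE(object@normalized)) {
    if (!"blue" %in% object@bands) return("normalized basis requires a blue band")
    # normalizeBasis() sets the blue max to exactly 1; averaging
    # normalized replicates whose blue peaks fall at different
    # wavelengths can only pull it below 1
    bmax <- max(v[, match("blue", object@bands)])
    if (bmax <= 0 || bmax > 1 + 1e-8)
      return("normalized flag set but blue-band maximum is not in (0, 1]")
  }
  TRUE
})

#' BasisSet: an ordered collection of basis spectra
#'
#' All member spectra share one excitation axis, one band set, one
#' normalization and calibration state, and have unique labels. This is
#' the endmember library handed to the unmixer.
#'
#' @slot spectra List of [BasisSpectrum-class] objects.
#' @seealso [BasisSet()], [syntheticBasisSet()], [buildDesignMatrix()]
#' @export
setClass("BasisSet", representation(spectra = "list"))

setValidity("BasisSet", function(object) {
  sp <- object@spectra
  if (length(sp) < 1L) return("BasisSet needs at least one spectrum")
  if (!all(vapply(sp, is, TRUE, "BasisSpectrum")))
    return("all members must be BasisSpectrum objects")
  labs <- vapply(sp, function(s) s@label, "")
  if (anyDuplicated(labs)) return("labels must be unique")
  ref <- sp[[1L]]
  for (s in sp[-1L]) {
    if (!isTRUE(all.equal(s@wavelengths, ref@wavelengths)))
      return("all members must share one excitation axis")
    if (!identical(s@bands, ref@bands))
      return("all members must share one emission-band set")
    if (!identical(s@normalized, ref@normalized))
      return("all members must share one normalization state")
    if (!identical(s@calibrated, ref@calibrated))
      return("all members must share one calibration state")
  }
  TRUE
})

#' CalibrationProfile: measured instrument envelope and channel scales
#'
#' The empirical stand-in for the wavelength-dependent excitation
#' envelope K, measured as the green-channel excitation spectrum of a
#' homogeneous FAD reference well (FAD's two-photon cross section being
#' nearly flat over 710--900 nm), plus one positive scale factor per
#' emission band derived from matched-power LED back-illumination (blue
#' fixed at 1).
#'
#' @slot wavelengths Excitation axis (nm).
#' @slot envelope Positive vector over the axis (arbitrary units).
#' @slot channelScale Named positive factors, one per band; blue == 1.
#' @slot floor Small positive guard used when flooring the envelope.
#' @seealso [measureReferenceEnvelope()], [applyCalibration()]
#' @export
setClass("CalibrationProfile",
         representation(wavelengths = "numeric", envelope = "numeric",
                        channelScale = "numeric", floor = "numeric"))

setValidity("CalibrationProfile", function(object) {
  msg <- .validExcitation(object@wavelengths)
  if (!is.null(msg)) return(msg)
  if (length(object@envelope) != length(object@wavelengths))
    return("envelope must have one value per wavelength")
  if (!all(is.finite(object@envelope)) || any(object@envelope <= 0))
    return("envelope must be strictly positive (after flooring)")
  cs <- object@channelScale
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    return("channelScale must be uniquely named by band")
  if (!all(is.finite(cs)) || any(cs <= 0))
    return("channelScale factors must be positive")
  if ("blue" %in% names(cs) && abs(cs[["blue"]] - 1) > 1e-12)
    return("channelScale for the blue band must be exactly 1")
  if (length(object@floor) != 1L || object@floor <= 0)
    return("floor must be a single positive number")
  TRUE
})

#' CoefficientMaps: per-pixel unmixing abundances
#'
#' The 3-D array \code{[row, col, component]} of non-negative NNLS
#' coefficients (arbitrary units, proportional to relative abundance).
#' After [scaleCoefficientMaps()] all maps are divided by the maximum of
#' the display-reference component (conventionally epithelium) and
#' \code{maxValues} records each component's resulting maximum -- the
#' "m.v." annotation of the grayscale panels.
#'
#' @slot coeffs 3-D non-negative array \code{[row, col, n_components]}.
#' @slot labels Component order.
#' @slot scaled Logical display-scaling flag.
#' @slot maxValues Named per-component maxima (filled at scaling).
#' @export
setClass("CoefficientMaps",
         representation(coeffs = "array", labels = "character",
                        scaled = "logical", maxValues = "numeric"))

setValidity("CoefficientMaps", function(object) {
  d <- object@coeffs
  if (length(dim(d)) != 3L)
    return("coeffs must be a 3-D array [row, col, component]")
  if (dim(d)[3L] != length(object@labels))
    return("3rd dimension must match number of labels")
  if (anyDuplicated(object@labels)) return("component labels must be unique")
  if (!all(is.finite(d)) || any(d < 0))
    return("coefficients must be finite and non-negative")
  TRUE
})

#' ResidualMap: per-pixel squared fit-error surface
#'
#' The squared Euclidean norm of the NNLS residual at every pixel,
#' pooled over all excitation wavelengths and used emission bands
#' (units: detector counts squared).
#'
#' @slot values Non-negative matrix, same spatial shape as the stack.
#' @export
setClass("ResidualMap", representation(values = "matrix"))

setValidity("ResidualMap", function(object) {
  if (!all(is.finite(object@values)) || any(object@values < 0))
    return("residual values must be finite and non-negative")
  TRUE
})

#' PhantomScene: synthetic tissue geometry with known ground truth
#'
#' Output of [generatePhantom()]: an integer label map (0 = background,
#' 1..k = component ids), the true per-component concentration maps, and
#' the generation parameters. Pure pixels are those whose concentration
#' mass sits entirely in one component; narrow (<= 2 px) linear mixing
#' zones separate regions.
#'
#' @slot labelMap Integer matrix of dominant component ids (0 background).
#' @slot concentrations 3-D array \code{[row, col, k]} of true abundances.
#' @slot labels Component names (order of the 3rd dimension).
#' @slot geometry Preset name.
#' @slot seed RNG seed used.
#' @export
setClass("PhantomScene",
         representation(labelMap = "matrix", concentrations = "array",
                        labels = "character", geometry = "character",
                        seed = "integer"))

setValidity("PhantomScene", function(object) {
  C <- object@concentrations
  if (length(dim(C)) != 3L) return("concentrations must be 3-D [row, col, k]")
  if (dim(C)[3L] != length(object@labels))
    return("concentrations 3rd dimension must match labels")
  if (!identical(dim(object@labelMap), dim(C)[1:2]))
    return("labelMap shape must match concentrations")
  if (any(C < 0) || !all(is.finite(C)))
    return("concentrations must be finite and non-negative")
  # on pure pixels the label must agree with the argmax concentration
  k <- dim(C)[3L]
  cm <- matrix(C, ncol = k)
  am <- max.col(cm, "first")
  mx <- cm[cbind(seq_len(nrow(cm)), am)]
  pure <- mx > 0 & (rowSums(cm) - mx) <= 1e-9 * pmax(mx, 1)
  lab <- as.vector(object@labelMap)
  if (any(lab[pure] != am[pure]))
    return("labelMap inconsistent with argmax concentration on pure pixels")
  TRUE
})
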