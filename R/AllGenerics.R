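#' @include AllClasses.R
NULL

#' Accessors for hyperunmix objects
#'
#' Small generic accessor family: \code{stackData} returns the raw 4-D
#' intensity array, \code{wavelengths} the excitation axis in nm,
#' \code{emissionBands} the band table (or band-name vector),
#' \code{componentLabels} the ordered component names, \code{stackMeta}
#' the free-form metadata list.
#'
#' @param object A package object.
#' @return See details per class.
#' @name accessors
#' @aliases stackData wavelengths emissionBands componentLabels stackMeta
NULL

#' @rdname accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("emissionBands", function(object) standardGeneric("emissionBands"))

#' @rdname accessors
#' @export
setGeneric("componentLabels", function(object) standardGeneric("componentLabels"))

#' @rdname accessors
#' @export
setGeneric("stackMeta", function(object) standardGeneric("stackMeta"))

#' @rdname accessors
#' @export
setMethod("stackData", "HyperStack", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("wavelengths", "HyperStack", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "BasisSpectrum", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "BasisSet",
          function(object) object@spectra[[1L]]@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "CalibrationProfile", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("emissionBands", "HyperStack", function(object) object@bands)

#' @rdname accessors
#' @export
setMethod("emissionBands", "BasisSpectrum", function(object) object@bands)

#' @rdname accessors
#' @export
setMethod("emissionBands", "BasisSet", function(object) object@spectra[[1L]]@bands)

#' @rdname accessors
#' @export
setMethod("componentLabels", "BasisSet",
          function(object) vapply(object@spectra, function(s) s@label, ""))

#' @rdname accessors
#' @export
setMethod("componentLabels", "CoefficientMaps", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("componentLabels", "PhantomScene", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("stackMeta", "HyperStack", function(object) object@meta)

#' Basis-spectrum accessors
#'
#' @param object A [BasisSpectrum-class] or [BasisSet-class].
#' @param label For \code{basisSpectrum}, which member to extract.
#' @return \code{basisValues}/\code{basisStd}: numeric matrices
#'   \code{[n_ex x n_bands]}; \code{basisLabel}: character;
#'   \code{basisSpectrum}: a [BasisSpectrum-class].
#' @name basis-accessors
NULL

#' @rdname basis-accessors
#' @export
setGeneric("basisValues", function(object) standardGeneric("basisValues"))
#' @rdname basis-accessors
#' @export
setGeneric("basisStd", function(object) standardGeneric("basisStd"))
#' @rdname basis-accessors
#' @export
setGeneric("basisLabel", function(object) standardGeneric("basisLabel"))
#' @rdname basis-accessors
#' @export
setGeneric("basisSpectrum", function(object, label) standardGeneric("basisSpectrum"))

#' @rdname basis-accessors
#' @export
setMethod("basisValues", "BasisSpectrum", function(object) object@values)
#' @rdname basis-accessors
#' @export
setMethod("basisStd", "BasisSpectrum", function(object) object@std)
#' @rdname basis-accessors
#' @export
setMethod("basisLabel", "BasisSpectrum", function(object) object@label)
#' @rdname basis-accessors
#' @export
setMethod("basisSpectrum", "BasisSet", function(object, label) {
  i <- match(label, componentLabels(object))
  if (is.na(i)) stop("no basis spectrum labelled '", label, "'", call. = FALSE)
  object@spectra[[i]]
})

#' Extract one component's abundance map
#'
#' @param object A [CoefficientMaps-class].
#' @param label Component name.
#' @return Numeric matrix of that component's per-pixel coefficients.
#' @export
setGeneric("componentMap", function(object, label) standardGeneric("componentMap"))

#' @rdname componentMap
#' @export
setMethod("componentMap", "CoefficientMaps", function(object, label) {
  i <- match(label, object@labels)
  if (is.na(i)) stop("no component labelled '", label, "'", call. = FALSE)
  object@coeffs[, , i]
})

#' Residual-map values
#'
#' @param object A [ResidualMap-class].
#' @return Non-negative numeric matrix of per-pixel squared residual norms.
#' @export
setGeneric("residualValues", function(object) standardGeneric("residualValues"))

#' @rdname residualValues
#' @export
setMethod("residualValues", "ResidualMap", function(object) object@values)

#' @export
setMethod("dim", "HyperStack", function(x) dim(x@data))

setMethod("show", "HyperStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperStack: %d x %d pixels, %d excitation wavelengths (%g-%g nm), %d bands (%s)\n",
              d[1L], d[2L], d[3L], min(object@wavelengths), max(object@wavelengths),
              d[4L], paste(object@bands$name, collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]", min(object@data), max(object@data)))
  if (length(object@meta)) cat("; meta:", paste(names(object@meta), collapse = ", "))
  cat("\n")
})

setMethod("show", "BasisSpectrum", function(object) {
  cat(sprintf("BasisSpectrum '%s': %d wavelengths x %d bands%s%s (sites %d, animals %d)\n",
              object@label, nrow(object@values), ncol(object@values),
              if (object@normalized) ", normalized" else "",
              if (object@calibrated) ", calibrated" else "",
              object@nSites, object@nAnimals))
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet: %d components [%s], %d wavelengths, bands %s%s\n",
              length(object@spectra),
              paste(componentLabels(object), collapse = ", "),
              length(wavelengths(object)),
              paste(emissionBands(object), collapse = "/"),
              if (object@spectra[[1L]]@normalized) ", normalized" else ""))
})

setMethod("show", "CalibrationProfile", function(object) {
  cat(sprintf("CalibrationProfile: %d wavelengths, envelope range [%.4g, %.4g], channel scales %s\n",
              length(object@wavelengths), min(object@envelope), max(object@envelope),
              paste(sprintf("%s=%.3g", names(object@channelScale),
                            object@channelScale), collapse = " ")))
})

setMethod("show", "CoefficientMaps", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("CoefficientMaps: %d x %d pixels, %d components [%s]%s\n",
              d[1L], d[2L], d[3L], paste(object@labels, collapse = ", "),
              if (object@scaled) " (display-scaled)" else ""))
  if (length(object@maxValues))
    cat("  max values:", paste(sprintf("%s=%.3g", names(object@maxValues),
                                       object@maxValues), collapse = " "), "\n")
})

setMethod("show", "ResidualMap", function(object) {
  v <- object@values
  cat(sprintf("ResidualMap: %d x %d, mean %.4g, max %.4g\n",
              nrow(v), ncol(v), mean(v), max(v)))
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene '%s': %d x %d, %d components [%s], seed %d\n",
              object@geometry, nrow(object@labelMap), ncol(object@labelMap),
              length(object@labels), paste(object@labels, collapse = ", "),
              object@seed))
})
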