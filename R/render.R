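#' @include AllClasses.R unmix.R
NULL

#' Rendering configuration
#'
#' @param clipFraction Fraction of the brightest pixels thresholded out
#'   per channel before scaling an RGB merge (default 0.0006, i.e. the
#'   highest 0.06\%); must lie in \eqn{[0, 0.01)}.
#' @param colormap Named list of RGB triplets in \eqn{[0,1]^3} used by
#'   [falseColorComposite()]; default epithelium = yellow,
#'   lamina_propria = white, collagen = blue, lymphatic = green.
#' @return A list of class \code{"RenderConfig"}.
#' @export
RenderConfig <- function(clipFraction = 0.0006,
                         colormap = list(epithelium = c(1, 1, 0),
                                         lamina_propria = c(1, 1, 1),
                                         collagen = c(0, 0, 1),
                                         lymphatic = c(0, 1, 0))) {
  if (clipFraction < 0 || clipFraction >= 0.01)
    stop("clipFraction must be in [0, 0.01)", call. = FALSE)
  if (any(vapply(colormap, function(c) any(c < 0 | c > 1), TRUE)))
    stop("colormap entries must be RGB triplets in [0, 1]", call. = FALSE)
  structure(list(clipFraction = clipFraction, colormap = colormap),
            class = "RenderConfig")
}

# Clip value = intensity of the pixel ranked ceiling((1 - f) * N) in
# ascending order; everything strictly above it is clipped ("saturated").
# Ties at the clip value all render full scale but are not counted as
# clipped. Returns the scaled channel in [0, 1] plus diagnostics.
.clipScale <- function(v, clipFraction) {
  n <- length(v)
  rank <- max(1L, ceiling((1 - clipFraction) * n))
  cv <- sort(v, partial = rank)[rank]
  if (cv <= 0) {
    # channel effectively empty (or clip lands on a zero pixel): fall
    # back to the channel max so a nonzero tail is still visible
    cv <- max(v)
    if (cv <= 0) return(list(scaled = v * 0, clipValue = 0, saturated = 0L))
  }
  list(scaled = pmin(v / cv, 1), clipValue = cv, saturated = sum(v > cv))
}

#' Thresholded RGB merge of a hyperspectral stack
#'
#' The basic visualization: for each of the red, green and blue bands,
#' average the frames in the selected excitation window, threshold out
#' the brightest \code{clipFraction} of pixels, scale the channel to
#' that clip value, and quantize half-up to 8 bits. A scalar selection
#' picks the nearest grid wavelength; a length-2 range averages all
#' frames inside it (e.g. a 25 nm window around a center wavelength).
#' The merge is invariant to scaling the whole stack by one positive
#' factor.
#'
#' @param stack A [HyperStack-class] with red, green and blue bands.
#' @param exSelection Wavelength (nm) or \code{c(lo, hi)} range.
#' @param cfg A [RenderConfig()].
#' @return Integer array \code{[rows x cols x 3]} (R, G, B) in 0..255,
#'   with attributes \code{clipValues} and \code{saturated} (per-channel
#'   count of pixels strictly above the clip value).
#' @export
rgbMerge <- function(stack, exSelection, cfg = RenderConfig()) {
  stopifnot(is(stack, "HyperStack"))
  wl <- stack@wavelengths
  if (length(exSelection) == 1L) {
    if (exSelection < min(wl) || exSelection > max(wl))
      stop("selected wavelength ", exSelection, " nm is outside the axis ",
           min(wl), "-", max(wl), " nm", call. = FALSE)
    sel <- which.min(abs(wl - exSelection))
  } else {
    sel <- which(wl >= min(exSelection) & wl <= max(exSelection))
    if (!length(sel))
      stop("excitation selection [", min(exSelection), ", ", max(exSelection),
           "] nm does not intersect the axis", call. = FALSE)
  }
  chans <- c("red", "green", "blue")
  bi <- match(chans, stack@bands$name)
  if (any(is.na(bi)))
    stop("RGB merge needs red, green and blue bands; missing: ",
         paste(chans[is.na(bi)], collapse = ", "), call. = FALSE)
  d <- dim(stack@data)
  out <- array(0L, c(d[1L], d[2L], 3L))
  clipValues <- numeric(3L); saturated <- integer(3L)
  for (c_ in 1:3) {
    sub <- stack@data[, , sel, bi[c_], drop = FALSE]
    avg <- apply(sub, 1:2, mean)
    cs <- .clipScale(as.vector(avg), cfg$clipFraction)
    out[, , c_] <- matrix(.quantize8(cs$scaled), d[1L], d[2L])
    clipValues[c_] <- cs$clipValue
    saturated[c_] <- cs$saturated
  }
  names(clipValues) <- names(saturated) <- chans
  structure(out, clipValues = clipValues, saturated = saturated)
}

#' Grayscale panel for one unmixed component
#'
#' The map is scaled from 0 to its own maximum and quantized to 8 bits;
#' the annotation is that maximum on the display scale (relative to the
#' epithelium maximum of 1), the "m.v." printed on each panel. An
#' all-zero map renders black with annotation 0.
#'
#' @param maps A display-scaled [CoefficientMaps-class].
#' @param label Component name.
#' @return List with \code{image} (integer matrix 0..255) and
#'   \code{maxValue}.
#' @export
componentGrayscale <- function(maps, label) {
  stopifnot(is(maps, "CoefficientMaps"))
  if (!isTRUE(maps@scaled))
    stop("maps must be display-scaled first; see scaleCoefficientMaps()",
         call. = FALSE)
  m <- componentMap(maps, label)
  mx <- max(m)
  if (mx <= 0)
    return(list(image = matrix(0L, nrow(m), ncol(m)), maxValue = 0))
  list(image = matrix(.quantize8(m / mx), nrow(m), ncol(m)), maxValue = mx)
}

#' False-color composite of unmixed components
#'
#' Each component map is scaled to its own maximum, tinted with its
#' configured color, summed across components, clipped to \eqn{[0, 1]}
#' per channel and quantized to 8 bits. All-zero components contribute
#' nothing.
#'
#' @param maps A display-scaled [CoefficientMaps-class].
#' @param cfg A [RenderConfig()] whose colormap covers every component.
#' @return Integer array \code{[rows x cols x 3]} in 0..255.
#' @export
falseColorComposite <- function(maps, cfg = RenderConfig()) {
  stopifnot(is(maps, "CoefficientMaps"))
  if (!isTRUE(maps@scaled))
    stop("maps must be display-scaled first; see scaleCoefficientMaps()",
         call. = FALSE)
  missingCol <- setdiff(maps@labels, names(cfg$colormap))
  if (length(missingCol))
    stop("no color configured for component(s): ",
         paste(missingCol, collapse = ", "), call. = FALSE)
  d <- dim(maps@coeffs)
  acc <- array(0, c(d[1L], d[2L], 3L))
  for (i in seq_along(maps@labels)) {
    m <- maps@coeffs[, , i]
    mx <- max(m)
    if (mx <= 0) next
    col <- cfg$colormap[[maps@labels[i]]]
    for (c_ in 1:3) acc[, , c_] <- acc[, , c_] + (m / mx) * col[c_]
  }
  out <- array(0L, dim(acc))
  out[] <- .quantize8(pmin(acc, 1))
  out
}

#' Write an 8-bit image to PNG
#'
#' @param img Integer matrix (grayscale) or \code{[rows x cols x 3]}
#'   array in 0..255, as produced by the rendering functions.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
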