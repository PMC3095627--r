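#' @include AllClasses.R
NULL

#' Construct a HyperStack
#'
#' Validates and wraps a 4-D intensity array \code{[row, col, excitation,
#' band]} with its excitation axis and emission-band table. Negative raw
#' values (amplifier offsets) are clipped to 0 with a message reporting
#' the clipped count; the clipped count is also recorded in
#' \code{meta$clipped_negative}.
#'
#' @param data 4-D numeric array of detector counts.
#' @param wavelengths Excitation wavelengths in nm, strictly increasing;
#'   defaults to [defaultExcitationAxis()] when its length matches.
#' @param bands Emission-band data.frame (\code{name, low_nm, high_nm});
#'   defaults to [defaultEmissionBands()] when the band count matches.
#' @param meta Named list of free-form metadata.
#' @param clipNegative Clip negative values to 0 (default \code{TRUE});
#'   with \code{FALSE} negative values are a validation error.
#' @return A validated [HyperStack-class].
#' @export
#' @examples
#' hs <- HyperStack(array(1, c(4, 4, 2, 3)), wavelengths = c(710, 715))
#' dim(hs)
HyperStack <- function(data, wavelengths = NULL, bands = NULL,
                       meta = list(), clipNegative = TRUE) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array [row, col, excitation, band]", call. = FALSE)
  if (is.null(wavelengths)) {
    if (dim(data)[3L] == 43L) wavelengths <- defaultExcitationAxis()
    else stop("wavelengths must be given when the excitation dimension is not 43",
              call. = FALSE)
  }
  if (is.null(bands)) {
    db <- defaultEmissionBands()
    if (dim(data)[4L] > nrow(db))
      stop("bands must be given for more than 3 emission bands", call. = FALSE)
    bands <- db[seq_len(dim(data)[4L]), , drop = FALSE]
  }
  .assertFinite(data, "data")
  nneg <- sum(data < 0)
  if (nneg > 0) {
    if (!clipNegative)
      stop(nneg, " negative intensities present and clipNegative = FALSE",
           call. = FALSE)
    message("HyperStack: clipped ", nneg, " negative value(s) to 0")
    data[data < 0] <- 0
    meta$clipped_negative <- nneg
  }
  storage.mode(data) <- "double"
  new("HyperStack", data = data, wavelengths = as.numeric(wavelengths),
      bands = bands, meta = meta)
}

#' Extract the spectrum of one pixel
#'
#' Returns a copy of the \code{[n_ex x n_bands]} spectrum at the given
#' pixel (1-based row/column, no wraparound: negative or out-of-range
#' indices are an error). Being a copy, mutating the return value never
#' affects the stack.
#'
#' @param stack A [HyperStack-class].
#' @param row,col 1-based pixel indices.
#' @return Numeric matrix \code{[n_ex x n_bands]} with dimnames
#'   (wavelengths, band names).
#' @export
pixelSpectrum <- function(stack, row, col) {
  stopifnot(is(stack, "HyperStack"))
  d <- dim(stack@data)
  if (!.isCount(row) || !.isCount(col) || row < 1 || col < 1 ||
      row > d[1L] || col > d[2L])
    stop(sprintf("pixel index (%s, %s) out of bounds for %d x %d frame",
                 format(row), format(col), d[1L], d[2L]), call. = FALSE)
  m <- stack@data[row, col, , ]
  dim(m) <- d[3:4]
  dimnames(m) <- list(format(stack@wavelengths), stack@bands$name)
  m
}

# Map a stack to the list of TIFF pages, excitation-major then band:
# page = (ex_index - 1) * n_bands + band_index.
.stackPages <- function(data) {
  d <- dim(data)
  pages <- vector("list", d[3L] * d[4L])
  for (i in seq_len(d[3L])) for (b in seq_len(d[4L])) {
    m <- data[, , i, b]
    dim(m) <- d[1:2]
    pages[[(i - 1L) * d[4L] + b]] <- m
  }
  pages
}

#' Save a HyperStack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered excitation-major then band
#' (\code{page = ex_index * n_bands + band_index} in 0-based terms). The
#' sidecar \code{<path>.json} records wavelengths, bands, metadata and
#' the storage encoding. TIFF samples are stored in \eqn{[0, 1]} with a
#' recorded scale: integer-valued stacks use 16-bit (or 32-bit above
#' 65535) samples and round-trip exactly; other stacks use 32-bit
#' samples scaled by the stack maximum and round-trip to within about
#' \code{2.4e-10} of that maximum.
#'
#' @param stack A valid [HyperStack-class].
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @seealso [loadHyperStack()]
#' @export
saveHyperStack <- function(stack, path) {
  stopifnot(is(stack, "HyperStack"))
  validObject(stack)
  d <- stack@data
  mx <- max(d)
  integral <- mx <= 2^32 - 1 && all(d == floor(d))
  if (integral) {
    scale <- if (mx <= 65535) 65535 else 2^32 - 1
    bits <- if (mx <= 65535) 16L else 32L
  } else {
    scale <- if (mx > 0) mx else 1
    bits <- 32L
  }
  pages <- lapply(.stackPages(d), function(m) m / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF at '", path, "': ",
         attr(ok, "condition")$message, call. = FALSE)
  sidecar <- list(
    wavelengths_nm = stack@wavelengths,
    bands = unname(apply(stack@bands, 1L,
                         function(r) list(r[["name"]], as.numeric(r[["low_nm"]]),
                                          as.numeric(r[["high_nm"]])))),
    shape = dim(d),
    dtype = if (integral) "integer" else "float",
    scale = scale,
    meta = stack@meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a HyperStack written by [saveHyperStack()]
#'
#' Checks that the TIFF page count equals \code{n_ex * n_bands} declared
#' by the sidecar and re-validates all axis invariants.
#'
#' @param path TIFF path; the sidecar is expected at \code{<path>.json}.
#' @return A validated [HyperStack-class].
#' @export
loadHyperStack <- function(path) {
  if (!file.exists(path))
    stop("no TIFF at '", path, "'", call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar: expected '", side, "' next to the TIFF", call. = FALSE)
  sc <- jsonlite::read_json(side, simplifyVector = FALSE)
  wl <- as.numeric(unlist(sc$wavelengths_nm))
  msg <- .validExcitation(wl)
  if (!is.null(msg)) stop("sidecar invalid: ", msg, call. = FALSE)
  bands <- do.call(rbind, lapply(sc$bands, function(b)
    data.frame(name = as.character(b[[1L]]), low_nm = as.numeric(b[[2L]]),
               high_nm = as.numeric(b[[3L]]), stringsAsFactors = FALSE)))
  nex <- length(wl); nb <- nrow(bands)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nex * nb)
    stop(sprintf("TIFF dialect error: %d pages found but sidecar declares %d wavelengths x %d bands = %d pages",
                 length(pages), nex, nb, nex * nb), call. = FALSE)
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  scale <- as.numeric(sc$scale %||% 1)
  data <- array(0, c(nr, nc, nex, nb))
  for (i in seq_len(nex)) for (b in seq_len(nb)) {
    pg <- pages[[(i - 1L) * nb + b]] * scale
    if (identical(sc$dtype, "integer")) pg <- round(pg)
    data[, , i, b] <- pg
  }
  meta <- lapply(sc$meta, function(x) if (is.list(x)) unlist(x) else x)
  HyperStack(data, wavelengths = wl, bands = bands, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a region-of-interest mask
#'
#' Reads a PNG mask (any nonzero pixel = inside) or accepts a logical
#' matrix directly. ROIs used for extraction must contain at least one
#' pixel.
#'
#' @param x PNG file path, or a logical/numeric matrix.
#' @return Logical matrix.
#' @export
readROIMask <- function(x) {
  if (is.character(x)) {
    img <- png::readPNG(x)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img > 0)
  }
  if (is.matrix(x)) return(x != 0 & !is.na(x))
  stop("ROI mask must be a PNG path or a matrix", call. = FALSE)
}

.checkROI <- function(roi, stack) {
  roi <- readROIMask(roi)
  d <- dim(stack@data)
  if (!identical(dim(roi), d[1:2]))
    stop(sprintf("ROI shape %d x %d does not match stack frame %d x %d",
                 nrow(roi), ncol(roi), d[1L], d[2L]), call. = FALSE)
  if (!any(roi)) stop("ROI is empty (no pixels selected)", call. = FALSE)
  roi
}
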