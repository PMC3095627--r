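#' @include AllClasses.R hyperstack.R
NULL

#' Canonical tissue component names
#'
#' The four GI tissue types whose excitation--emission signatures form
#' the standard basis set: epithelium, lamina propria, collagen and
#' lymphatic tissue. Labels are open strings, so user-defined components
#' can be added freely; these are merely the shipped defaults.
#' @export
TISSUE_LABELS <- c("epithelium", "lamina_propria", "collagen", "lymphatic")

#' Construct a BasisSpectrum
#'
#' @param label Tissue name.
#' @param values Matrix \code{[n_ex x n_bands]} of non-negative values.
#' @param wavelengths Excitation axis (nm).
#' @param bands Band names (column order); default the first
#'   \code{ncol(values)} of blue/green/red.
#' @param std Optional same-shape standard-deviation matrix (default 0).
#' @param nSites,nAnimals Provenance counts.
#' @param normalized,calibrated State flags.
#' @return A validated [BasisSpectrum-class].
#' @export
BasisSpectrum <- function(label, values, wavelengths, bands = NULL,
                          std = NULL, nSites = 1L, nAnimals = 1L,
                          normalized = FALSE, calibrated = FALSE) {
  values <- as.matrix(values)
  if (is.null(bands)) bands <- c("blue", "green", "red")[seq_len(ncol(values))]
  if (is.null(std)) std <- matrix(0, nrow(values), ncol(values))
  new("BasisSpectrum", label = label, values = values, std = as.matrix(std),
      wavelengths = as.numeric(wavelengths), bands = bands,
      nSites = as.integer(nSites), nAnimals = as.integer(nAnimals),
      normalized = normalized, calibrated = calibrated)
}

#' Construct a BasisSet
#'
#' @param ... [BasisSpectrum-class] objects, or a single list of them.
#' @return A validated [BasisSet-class].
#' @export
BasisSet <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && is.list(sp[[1L]]) && !is(sp[[1L]], "BasisSpectrum"))
    sp <- sp[[1L]]
  new("BasisSet", spectra = sp)
}

#' Extract a mean excitation--emission spectrum from an ROI
#'
#' Averages all ROI pixels of the stack at each excitation wavelength
#' and emission band (the image-guided spectroscopy step: small regions
#' are selected by morphology and their pixels averaged). The sample
#' standard deviation over ROI pixels is recorded alongside (0 for a
#' single-pixel ROI).
#'
#' @param stack A [HyperStack-class].
#' @param roi ROI mask (logical matrix or PNG path); must be non-empty.
#' @param label Tissue label for the resulting spectrum.
#' @return An unnormalized [BasisSpectrum-class].
#' @export
extractROISpectrum <- function(stack, roi, label) {
  stopifnot(is(stack, "HyperStack"))
  roi <- .checkROI(roi, stack)
  d <- dim(stack@data)
  n <- sum(roi)
  vals <- matrix(0, d[3L], d[4L])
  stds <- matrix(0, d[3L], d[4L])
  for (i in seq_len(d[3L])) for (b in seq_len(d[4L])) {
    px <- stack@data[, , i, b][roi]
    vals[i, b] <- mean(px)
    stds[i, b] <- if (n > 1L) stats::sd(px) else 0
  }
  cal <- isTRUE(stack@meta$calibrated)
  BasisSpectrum(label, vals, stack@wavelengths, bands = stack@bands$name,
                std = stds, calibrated = cal)
}

#' Normalize a basis spectrum to its blue-band maximum
#'
#' Divides every entry (values and std alike) by the maximum of the blue
#' emission channel's excitation spectrum, so the blue peak is exactly 1
#' while the relative amplitudes of all bands are preserved. Overall
#' signal amplitude varies with imaging depth, so each site's spectrum
#' is normalized this way before averaging across sites and animals.
#' Idempotent and scale-invariant.
#'
#' @param spec A [BasisSpectrum-class] with a non-zero blue column.
#' @return The normalized [BasisSpectrum-class].
#' @export
normalizeBasis <- function(spec) {
  stopifnot(is(spec, "BasisSpectrum"))
  bi <- match("blue", spec@bands)
  if (is.na(bi))
    stop("cannot normalize: spectrum has no blue band", call. = FALSE)
  m <- max(spec@values[, bi])
  if (m <= 0)
    stop("cannot normalize '", spec@label, "': blue column is all zero",
         call. = FALSE)
  initialize(spec, values = spec@values / m, std = spec@std / m,
             normalized = TRUE)
}

#' Average normalized basis spectra across sites/animals
#'
#' Elementwise mean and sample standard deviation (n-1 denominator)
#' across replicate normalized spectra of the same tissue type; sites
#' are pooled equally. Provenance counts are summed.
#'
#' @param specs List of normalized [BasisSpectrum-class] objects sharing
#'   one label and shape.
#' @return The aggregated [BasisSpectrum-class] (normalized).
#' @export
aggregateBases <- function(specs) {
  if (is(specs, "BasisSpectrum")) specs <- list(specs)
  if (length(specs) < 1L) stop("need at least one spectrum", call. = FALSE)
  ref <- specs[[1L]]
  for (s in specs) {
    if (!is(s, "BasisSpectrum")) stop("inputs must be BasisSpectrum objects",
                                      call. = FALSE)
    if (!identical(s@label, ref@label))
      stop("mixed labels: '", s@label, "' vs '", ref@label, "'", call. = FALSE)
    if (!identical(dim(s@values), dim(ref@values)))
      stop("mixed shapes across replicates", call. = FALSE)
    if (!isTRUE(s@normalized))
      stop("all spectra must be normalized before aggregation; see normalizeBasis()",
           call. = FALSE)
  }
  arr <- simplify2array(lapply(specs, function(s) s@values))
  mean_ <- apply(arr, 1:2, mean)
  std_ <- if (length(specs) > 1L) apply(arr, 1:2, stats::sd)
          else matrix(0, nrow(mean_), ncol(mean_))
  initialize(ref, values = mean_, std = std_,
             nSites = sum(vapply(specs, function(s) s@nSites, 1L)),
             nAnimals = sum(vapply(specs, function(s) s@nAnimals, 1L)))
}

#' Write / read a BasisSet as TSV tables with JSON headers
#'
#' One \code{<label>.tsv} per component (columns: \code{wavelength_nm},
#' one per band, then \code{std_<band>}) plus \code{<label>.json} with
#' label, provenance and state flags.
#'
#' @param basis A [BasisSet-class].
#' @param dir Directory (created if needed).
#' @return \code{writeBasisSet}: \code{dir} invisibly;
#'   \code{readBasisSet}: a [BasisSet-class].
#' @export
writeBasisSet <- function(basis, dir) {
  stopifnot(is(basis, "BasisSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in basis@spectra) {
    tab <- data.frame(wavelength_nm = s@wavelengths,
                      s@values, s@std, check.names = FALSE)
    names(tab) <- c("wavelength_nm", s@bands, paste0("std_", s@bands))
    utils::write.table(tab, file.path(dir, paste0(s@label, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(label = s@label, bands = s@bands, n_sites = s@nSites,
           n_animals = s@nAnimals, normalized = s@normalized,
           calibrated = s@calibrated),
      file.path(dir, paste0(s@label, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname writeBasisSet
#' @export
readBasisSet <- function(dir) {
  if (!dir.exists(dir))
    stop("no basis directory at '", dir, "'", call. = FALSE)
  heads <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(heads)) stop("no basis headers (*.json) in '", dir, "'",
                           call. = FALSE)
  sp <- lapply(heads, function(h) {
    hd <- jsonlite::read_json(h, simplifyVector = TRUE)
    tab <- utils::read.delim(sub("\\.json$", ".tsv", h), check.names = FALSE)
    bands <- as.character(hd$bands)
    BasisSpectrum(hd$label, as.matrix(tab[, bands, drop = FALSE]),
                  wavelengths = tab$wavelength_nm, bands = bands,
                  std = as.matrix(tab[, paste0("std_", bands), drop = FALSE]),
                  nSites = hd$n_sites, nAnimals = hd$n_animals,
                  normalized = isTRUE(hd$normalized),
                  calibrated = isTRUE(hd$calibrated))
  })
  BasisSet(sp)
}

#' Synthetic four-tissue basis set
#'
#' A packaged, clearly synthetic endmember library for tests and demos:
#' four smooth parametric excitation--emission signatures qualitatively
#' shaped like the canonical GI tissue types. Epithelium is
#' blue-dominant at short excitation wavelengths (NADH-like) with a
#' flat moderate green channel (FAD-like); lamina propria adds a
#' short-wavelength red peak (blood porphyrin); collagen is almost
#' entirely blue and rises with excitation wavelength (SHG transmitted
#' only above roughly 780 nm); lymphatic tissue is broad and similar
#' across all three bands. These curves are generated from closed-form
#' shapes, not digitized from any measured figure.
#'
#' @param wavelengths Excitation axis (default [defaultExcitationAxis()]).
#' @param normalized Return blue-max-1 normalized spectra (default
#'   \code{FALSE}: raw arbitrary units).
#' @return A [BasisSet-class] with components
#'   \code{epithelium, lamina_propria, collagen, lymphatic}.
#' @export
syntheticBasisSet <- function(wavelengths = defaultExcitationAxis(),
                              normalized = FALSE) {
  wl <- as.numeric(wavelengths)
  g <- function(mu, s) exp(-((wl - mu) / s)^2)
  sig <- function(mu, s) 1 / (1 + exp(-(wl - mu) / s))
  mk <- function(label, blue, green, red)
    BasisSpectrum(label, cbind(blue, green, red), wl,
                  bands = c("blue", "green", "red"))
  sp <- list(
    mk("epithelium",
       blue = 1.00 * g(730, 60),
       green = 0.45 * (0.75 + 0.25 * g(830, 140)),
       red = 0.06 + 0 * wl),
    mk("lamina_propria",
       blue = 0.70 * g(748, 70),
       green = 0.52 * g(765, 95),
       red = 0.65 * g(722, 42) + 0.05),
    mk("collagen",
       blue = 0.95 * sig(800, 24),
       green = 0.015 + 0 * wl,
       red = 0.008 + 0 * wl),
    mk("lymphatic",
       blue = 0.50 * g(780, 120),
       green = 0.46 * g(795, 125),
       red = 0.42 * g(770, 115)))
  bs <- BasisSet(sp)
  if (normalized)
    bs <- BasisSet(lapply(bs@spectra, normalizeBasis))
  bs
}
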