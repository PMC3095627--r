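#' @include unmix.R render.R phantom.R
NULL

#' Run the full unmixing pipeline from a configuration
#'
#' Orchestrates calibrate -> basis -> unmix -> residuals -> render as
#' one logged, reproducible run. The configuration is a named list (or
#' a YAML file path) with blocks:
#' \describe{
#'   \item{stack}{Path to a saved [HyperStack-class] TIFF, \emph{or}}
#'   \item{simulate}{\code{list(geometry, shape, seed, noise =
#'     list(kind, peak_counts, read_sigma), envelope = "parametric" or
#'     numeric)} to generate the input stack in place.}
#'   \item{basis}{Path to a basis directory ([readBasisSet()]) or
#'     \code{"synthetic"} for the packaged [syntheticBasisSet()].}
#'   \item{fad_scan}{Optional path to a reference-well stack; when
#'     present a [CalibrationProfile-class] is measured and saved
#'     (unmixing still consumes uncalibrated spectra).}
#'   \item{unmix}{\code{list(bands, reference, free_band_amplitude)}.}
#'   \item{render}{\code{list(clip_fraction, rgb_wavelength)}.}
#'   \item{out}{Output directory.}
#' }
#' Outputs: coefficient + residual TIFFs, rendered PNGs, and
#' \code{manifest.json} recording the config, package version,
#' per-stage timings, warnings, residual summary statistics and the
#' md5 of every numerical output. Re-running with an identical config
#' reproduces byte-identical coefficient and residual files.
#'
#' @param config Named list or path to a YAML file.
#' @return The manifest, invisibly (also written to the output dir).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: '", config, "'", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  out <- config$out %||% stop("config needs an 'out' directory", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "hyperunmix",
                   version = as.character(utils::packageVersion("hyperunmix")),
                   config = config, stages = list(), warnings = character(0))
  warn <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) { warn(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    manifest$stages[[name]] <<- list(elapsed_s = round(
      proc.time()[["elapsed"]] - t0, 3))
    val
  }

  basis <- stage("basis", {
    b <- config$basis %||% "synthetic"
    bs <- if (identical(b, "synthetic")) syntheticBasisSet()
          else readBasisSet(b)
    if (!bs@spectra[[1L]]@normalized)
      bs <- BasisSet(lapply(bs@spectra, normalizeBasis))
    bs
  })

  stack <- stage("input", {
    if (!is.null(config$stack)) {
      loadHyperStack(config$stack)
    } else if (!is.null(config$simulate)) {
      sm <- config$simulate
      env <- sm$envelope
      wl <- wavelengths(basis)
      env <- if (is.null(env)) NULL
             else if (identical(env, "parametric")) parametricEnvelope(wl)
             else as.numeric(env)
      nm <- if (is.null(sm$noise)) noiseModel("none")
            else noiseModel(sm$noise$kind %||% "none",
                            peakCounts = sm$noise$peak_counts %||% 1000,
                            readSigma = sm$noise$read_sigma %||% 0)
      scene <- generatePhantom(sm$geometry %||% "crypts",
                               shape = as.integer(sm$shape %||% c(128L, 128L)),
                               basis = basis, seed = sm$seed %||% 0L)
      st <- forwardSimulate(scene, basis, envelope = env, noise = nm,
                            seed = sm$seed %||% 0L)
      saveHyperStack(st, file.path(out, "stack.tif"))
      st
    } else stop("config needs either 'stack' or 'simulate'", call. = FALSE)
  })

  if (!is.null(config$fad_scan)) {
    stage("calibrate", {
      fad <- loadHyperStack(config$fad_scan)
      roi <- matrix(TRUE, dim(fad)[1L], dim(fad)[2L])
      cal <- measureReferenceEnvelope(fad, roi)
      saveCalibration(cal, file.path(out, "calibration.json"))
      cal
    })
  }

  ucfg <- UnmixConfig(
    bandsUsed = config$unmix$bands %||% c("blue", "green"),
    displayReference = config$unmix$reference %||% "epithelium",
    freeBandAmplitude = isTRUE(config$unmix$free_band_amplitude))
  fit <- stage("unmix", unmixStack(stack, basis, ucfg))
  maps <- stage("scale", scaleCoefficientMaps(fit$maps, ucfg))
  stage("save_maps", saveCoefficientMaps(maps, fit$residual, out))

  rcfg <- RenderConfig(clipFraction = config$render$clip_fraction %||% 0.0006)
  stage("render", {
    for (lab in componentLabels(maps)) {
      pan <- componentGrayscale(maps, lab)
      writeImagePNG(pan$image, file.path(out, paste0("component_", lab, ".png")))
    }
    if (all(componentLabels(maps) %in% names(rcfg$colormap)))
      writeImagePNG(falseColorComposite(maps, rcfg),
                    file.path(out, "composite.png"))
    if (all(c("red", "green", "blue") %in% stack@bands$name)) {
      wlsel <- config$render$rgb_wavelength %||% 740
      writeImagePNG(rgbMerge(stack, wlsel, rcfg),
                    file.path(out, "rgb_merge.png"))
    }
  })

  rv <- residualValues(fit$residual)
  manifest$residual_summary <- list(
    total = sum(rv), mean = mean(rv),
    p99 = as.numeric(stats::quantile(rv, 0.99)))
  manifest$clipped_negative <- stack@meta$clipped_negative %||% 0L
  files <- sort(list.files(out, pattern = "\\.(tif|png|json)$"))
  files <- setdiff(files, "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
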