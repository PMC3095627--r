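Package: hyperunmix
Title: Excitation-Scanning Hyperspectral Two-Photon Image Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for excitation-scanning hyperspectral
    two-photon microscopy of intrinsic tissue contrast. Reads and writes
    4-D hyperspectral stacks (y x x x excitation wavelength x emission
    band) as multi-page TIFF with a JSON metadata sidecar, calibrates
    spectra against a reference-fluorophore (FAD) scan to remove the
    instrument's wavelength-dependent excitation envelope, extracts and
    aggregates per-tissue excitation-emission basis spectra from regions
    of interest, unmixes stacks pixel-by-pixel into tissue abundance
    maps by non-negative least squares, maps fit residuals, and renders
    thresholded RGB merges, per-component grayscale panels and
    false-color composites. Includes a synthetic gastrointestinal-tissue
    phantom generator with known ground truth (crypt, villus, Peyer's
    patch, lesion and checkerboard geometries; Poisson shot noise) so
    the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
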