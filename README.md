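# hyperunmix

Excitation-scanning hyperspectral two-photon microscopy resolves fresh,
unstained tissue at subcellular resolution using only intrinsic contrast:
autofluorescence from NADH, FAD, porphyrins and phospholipids, plus second
harmonic generation (SHG) from collagen. Scanning the excitation wavelength
(710–920 nm in 5 nm steps) while collecting three fixed emission bands
(blue 350–505 nm, green 505–560 nm, red 560–650 nm) yields an excitation
spectrum per pixel per band. Because different tissue types carry different
fluorophore mixtures, those spectra act as signatures: fitting each pixel as
a non-negative combination of a few tissue *basis spectra* segments the image
into tissue-type abundance maps — an "instant histology" of fresh tissue,
analogous to specific staining but non-destructive and depth-resolved.

`hyperunmix` is an R package implementing that analysis chain for
gastrointestinal (and similar) tissue imaging:

- **Stack I/O** — 4-D stacks `[row, col, excitation, band]` as multi-page
  TIFF with a JSON metadata sidecar (`HyperStack`, `saveHyperStack()`,
  `loadHyperStack()`).
- **Calibration** — the instrument's wavelength-dependent excitation
  envelope *K(λ)* (laser power, pulse width, dispersion, NA) is measured
  empirically as the green-channel excitation spectrum of a homogeneous FAD
  reference well, whose two-photon cross section is nearly flat over this
  range; dividing by it removes *K* from all channels
  (`measureReferenceEnvelope()`, `applyCalibration()`). Per-band detector
  scale factors come from matched-power LED readings
  (`channelScaleFactors()`).
- **Basis spectra** — ROI-mean excitation–emission signatures, normalized to
  the blue channel's excitation maximum, then averaged across sites and
  animals (`extractROISpectrum()`, `normalizeBasis()`, `aggregateBases()`).
  A synthetic four-tissue library is packaged (`syntheticBasisSet()`).
- **Unmixing** — per-pixel non-negative least squares (in-package
  Lawson–Hanson active set, `nnlsSolve()`) on the concatenated blue+green
  excitation spectra, giving one coefficient per tissue component per pixel
  plus the squared residual norm (`unmixStack()`); display scaling sets the
  epithelium maximum to 1 (`scaleCoefficientMaps()`).
- **Rendering** — thresholded RGB merges (clipping the brightest 0.06 % of
  pixels per channel), per-component grayscale panels with max-value
  annotation, and false-color composites (`rgbMerge()`,
  `componentGrayscale()`, `falseColorComposite()`).
- **Synthetic phantoms** — ground-truth scenes (crypts, villi, Peyer's
  patch, lesion, checkerboard) pushed through the linear forward model
  `s[i,b] = K(λ_i) · Σ_j C_j · S_j(λ_i, b)` with Poisson shot noise
  (`generatePhantom()`, `forwardSimulate()`, `recoveryReport()`), so every
  stage is testable end to end.
- **Pipeline** — `runPipeline()` orchestrates a configured, logged,
  byte-reproducible run from a YAML or list config; a thin CLI wrapper lives
  at `inst/scripts/hyperunmix.R`.

The model: detected fluorescence at each pixel is a linear sum over species,
`F_mix(λ_ex, band) = K(λ_ex) · Σ_j C_j η_j φ_j σ_j(λ_ex, band)`, with *C* the
concentration and *η, φ, σ* quantum efficiency, collection efficiency and
two-photon cross section, lumped empirically into each tissue signature.
Because *K* multiplies basis spectra and measured data identically, unmixing
is performed on **uncalibrated** spectra; calibration is for interpretation
and plotting of the signatures themselves.

## Worked example

```r
library(hyperunmix)

basis <- syntheticBasisSet(normalized = TRUE)
scene <- generatePhantom("crypts", c(96, 96), basis, seed = 0)
stack <- forwardSimulate(scene, basis,
                         noise = noiseModel("poisson", 1000), seed = 0)
stack
#> HyperStack: 96 x 96 pixels, 43 excitation wavelengths (710-920 nm),
#>   3 bands (blue, green, red)
#>   intensity range [0, 1122]; meta: phantom, noise, sim_seed, count_scale

fit  <- unmixStack(stack, basis)            # blue+green NNLS per pixel
maps <- scaleCoefficientMaps(fit$maps)      # epithelium max -> 1
maps
#> CoefficientMaps: 96 x 96 pixels, 4 components [epithelium,
#>   lamina_propria, collagen, lymphatic] (display-scaled)
#>   max values: epithelium=1 lamina_propria=1 collagen=1 lymphatic=0.99

rep <- recoveryReport(scene, fit$maps)
print(rep$perComponent, digits = 3)
#>            label pearson_r    rmse   gauge
#> 1     epithelium     1.000 0.00918 0.00100
#> 2 lamina_propria     1.000 0.00862 0.00101
#> 3       collagen     1.000 0.00195 0.00100
#> 4      lymphatic     0.999 0.00390 0.00101
```

At a photon budget of 1000 peak counts, each recovered component map
correlates with its true concentration map at r ≥ 0.999; the gauge column is
the arbitrary per-component scalar (abundances are relative units) fixed by
least squares before computing RMSE. The argmax tissue label is correct on
100 % of pure-region pixels here. `writeImagePNG(falseColorComposite(maps),
"composite.png")` renders the segmentation (epithelium yellow, lamina
propria white, collagen blue, lymphatic green);
`componentGrayscale(maps, "collagen")` gives a Fig.-style panel with its
"m.v." annotation.

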