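---
title: "Methods: excitation-scanning hyperspectral unmixing in hyperunmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excitation-scanning hyperspectral unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperunmix)
```

## The measurement and the model

An excitation-scanning two-photon acquisition tunes the laser over
710–920 nm in 5 nm steps (43 wavelengths) while three photomultipliers
collect fixed emission bands (blue 350–505 nm, green 505–560 nm, red
560–650 nm). Each 2-D frame therefore carries a 43 × 3 excitation–emission
spectrum per pixel, stored here as a `HyperStack` — a 4-D array
`[row, col, excitation, band]` in detector counts.

The package assumes the standard linear mixing model for intrinsic
contrast: the signal at a pixel is

$$F(\lambda_i, b) \;=\; K(\lambda_i)\; \sum_j C_j \, S_j(\lambda_i, b),$$

where $C_j \ge 0$ is the (relative) concentration of tissue component $j$,
$S_j$ its lumped excitation–emission signature (absorbing quantum
efficiency, collection efficiency and two-photon cross section), and
$K(\lambda)$ a wavelength-dependent instrument envelope collecting laser
power, pulse width, repetition rate, dispersion, NA and the wavelength
itself. Two consequences drive the design:

* $K$ multiplies basis spectra and measured data identically, so it cancels
  in the fit. Unmixing therefore runs on **uncalibrated** spectra, and the
  package refuses to mix a calibrated basis with an uncalibrated stack (or
  vice versa) rather than silently producing biased coefficients.
* $K$ still distorts the *shape* of signatures for interpretation, so it is
  measured empirically — never evaluated from instrument constants — as the
  green-channel excitation spectrum of a homogeneous FAD well
  (`measureReferenceEnvelope()`), FAD's two-photon response being
  approximately flat over this range. We divide by the raw ROI-mean
  spectrum without smoothing; with $\ge 1000$ ROI pixels the Monte-Carlo
  error of the mean is well below 1 % and smoothing would only risk biasing
  narrow envelope structure.

## Calibration details

`applyCalibration()` computes
`out[i, b] = x[i, b] / envelope[i] * channelScale[b]`. The envelope is
guarded by a floor of $10^{-6} \times \max(\text{envelope})$: values at or
below it (possible at range edges where laser power collapses) are raised
to the floor with a warning instead of producing unbounded quotients.
Channel scale factors come from matched-power LED back-illumination as
`reading[blue] / reading[b]`, with blue pinned to exactly 1 so the blue
channel is the amplitude reference throughout.

For in-model (zero-residual) data, calibrating both stack and basis leaves
the NNLS coefficients unchanged up to one positive scalar per component
(the basis renormalization); this exact invariance is asserted on the
noiseless checkerboard phantom. For noisy data the division reweights
wavelengths and the equality is only approximate — one more reason the
pipeline unmixes uncalibrated spectra.

## Basis-spectrum protocol

Signatures are extracted as ROI means with per-entry sample standard
deviations (n−1 denominator; a single-pixel ROI reports 0). Because overall
amplitude varies with imaging depth while spectral shape is stable, each
site's spectrum is normalized **before** averaging: `normalizeBasis()`
divides by the maximum of the blue channel's excitation spectrum
(preserving relative band amplitudes), and `aggregateBases()` refuses
unnormalized inputs, enforcing the ordering through the `normalized` flag.
Sites are pooled equally across animals — the provenance counts are
recorded, but no animal-level weighting is applied. Note one small
algebraic fact the classes encode: normalization sets the blue maximum to
exactly 1, while the *average* of normalized replicates whose blue peaks
fall at different wavelengths can only have a blue maximum ≤ 1; the
validity check allows exactly that range.

Tissue labels are open strings so residual-guided refinement can introduce
new components without code changes; the canonical four
(`TISSUE_LABELS`) are epithelium, lamina propria, collagen and lymphatic
tissue.

`syntheticBasisSet()` ships a clearly synthetic endmember library built
from closed-form shapes: epithelium blue-dominant at short excitation
(NADH-like) with a flat moderate green channel (FAD-like); lamina propria
with a short-wavelength red peak (blood porphyrin); collagen almost purely
blue and rising with wavelength (SHG, transmitted only above ~780 nm);
lymphatic broad and similar across bands (phospholipid-like). These curves
are not digitized from any measured figure; they exist so tests and demos
have a realistic, well-conditioned basis.

## Unmixing

Each pixel's spectra over the used bands are concatenated into one vector
(blue then green by default, 86 entries on the default axis) and fit by
non-negative least squares against the same concatenation of the basis
spectra. The red channel is excluded by default: its relative amplitude
varies strongly with depth and blood content, degrading fits; it can be
opted in via `UnmixConfig(bandsUsed = ...)`, optionally together with
`freeBandAmplitude = TRUE`, which gives each non-blue band one free
positive per-pixel multiplier estimated by alternating NNLS over
coefficients and multipliers (initialized at 1, stopping when the residual
improves by < 1e-8 or after 50 iterations).

The NNLS solver is an in-package Lawson–Hanson active-set implementation
run on the normal equations: the Gram matrix $A^\top A$ is computed once
per stack and shared by all pixels, which makes the per-pixel cost a few
$k \times k$ solves ($k$ = number of components, typically 4). Tolerances:
a coefficient enters the active set only while its gradient component
exceeds $10^{-10} \max|A^\top b|$; residuals are always recomputed against
the original $(A, b)$ rather than from the normal equations, so reported
residual maps are accurate to machine precision (an all-zero pixel yields
exactly zero coefficients and zero residual). On rank-deficient designs the
active-set order makes the returned solution deterministic;
`buildDesignMatrix()` warns when the design's condition number exceeds
$10^8$, flagging possible non-uniqueness among equal-residual solutions.
The solver is verified in two independent ways: against exhaustive
enumeration of all $2^k$ active-set supports, and against
`pracma::lsqnonneg`, with Karush–Kuhn–Tucker optimality asserted at every
returned solution.

Coefficients are relative abundances in arbitrary units. For display,
`scaleCoefficientMaps()` divides all maps by the maximum of the reference
component (epithelium by default), so each map's recorded maximum — the
"m.v." annotation of the grayscale panels — reads as abundance relative to
epithelium. The per-pixel squared Euclidean residual norm, pooled over all
wavelengths and used bands, is returned as a `ResidualMap`; high-residual
structures signal out-of-model components (an effect the tests reproduce by
injecting a fifth spectral component, which strictly increases the total
residual).

## Rendering conventions

RGB merges average the frames in the selected excitation window (a scalar
picks the nearest grid wavelength; a range, e.g. 25 nm, is an unweighted
mean), then scale each channel to a rank-based clip value: the pixel ranked
$\lceil (1-f) N \rceil$ in ascending order, with $f$ = 0.0006 by default
(the brightest 0.06 %). Pixels strictly above the clip value are the ones
clipped ("saturated"), which on an all-distinct 400 × 400 frame is exactly
96 pixels; the pixel *at* the clip value also renders full scale but is not
counted as clipped, and ties at the clip value all saturate — a
deterministic convention. Quantization to 8 bits rounds half-up. Merges are
invariant to scaling the whole stack by one positive factor. The clip rank
is computed on the averaged frame, not per raw frame. False-color
composites tint each component map (scaled to its own maximum) with its
configured color — epithelium yellow, lamina propria white, collagen blue,
lymphatic green — summing and clipping per channel; all-zero components
contribute nothing.

## The phantom generator

`generatePhantom()` produces ground-truth scenes at any size ≥ 32 × 32,
deterministically from (geometry, shape, seed):

* `checkerboard` — pure single-component blocks, concentrations ∈ {0, 1},
  no mixing zones: the in-model identifiability fixture (noiseless
  simulate → unmix recovers concentrations to machine precision with zero
  residual).
* `crypts` — epithelial rings (crypts of Lieberkühn en face, radius about a
  tenth of the frame, dark lumina) in a lamina-propria matrix crossed by
  collagen fibers (random-walk strands) and lymphatic speckle. The
  epithelial pixel fraction lands in 0.05–0.6 across seeds.
* `villi` — ellipses with a 2–3 px epithelial rim and lamina-propria core
  containing sparse lymphatic cells; background (lumen) dark, essentially
  collagen-free.
* `peyer` — a dense lymphatic field with multiplicative texture plus bright
  lymphocyte disks, crossed by a collagen network.
* `lesion` — an irregular epithelial overgrowth (union of jittered disks)
  with collagen strands and lymphatic pockets in lamina propria.

All presets except the checkerboard pass each concentration map through a
3 × 3 mean filter, creating ≤ 2 px linear mixing zones at boundaries so
partial-volume behavior is exercised deliberately; pixels whose
concentration mass stays in one component are "pure" and are the domain of
the argmax-accuracy metric.

`forwardSimulate()` applies the linear model under a chosen envelope
(flat, measured, or the optional parametric form
$K \propto P(\lambda)^2/(\tau_p f_p) \times (NA^2/\lambda)^2$ normalized to
unit mean — a documented stand-in used only by the simulator). Noise is
shot noise on the detected signal: the noiseless stack is rescaled so its
brightest pixel has expectation `peakCounts`, then Poisson-sampled
(optionally plus clipped Gaussian read noise). The default
`peakCounts = 1000` is a typical photon budget for a 60 s wavelength scan
of autofluorescence at 1–3 mW; no measured SNR is being matched. Noise is
applied after envelope multiplication — the standard photon-counting
assumption.

What the phantoms do **not** emulate: optical sectioning and PSF blur,
depth-dependent attenuation, sample motion during a scan, and the
orientation dependence of SHG. Passing recovery tests therefore shows the
estimator chain is correct under the stated model, not that real-tissue
residual sources are negligible; on real data those effects surface in the
residual map rather than in simulation.

`recoveryReport()` fixes the per-component scale gauge (abundances are
relative) by the least-squares scalar before computing RMSE, and reports
per-component Pearson r plus argmax label accuracy on pure pixels.

## File formats and numerical storage

Stacks are multi-page grayscale TIFF (page = excitation-major then band)
plus a JSON sidecar holding wavelengths, bands, shape, metadata and the
storage encoding — deliberately a trivial dialect rather than OME-XML. The
R TIFF writer stores samples in [0, 1], so the sidecar records a scale:
integer-valued stacks are stored as 16-bit (or 32-bit above 65535) samples
and round-trip bit-exactly; other stacks are stored as 32-bit samples
scaled by the stack maximum and round-trip within ~2.4e-10 of that maximum
(near-zero pixels carry that absolute, not relative, guarantee). Negative
raw values (amplifier offsets) are clipped to 0 at construction with a
logged count, since the model is nonnegative and no offset convention is
recorded with the data. Basis sets are TSV + JSON per component;
calibration profiles and run manifests are JSON. Everything is
byte-deterministic given config and seeds, which the pipeline tests assert
by hashing outputs across reruns.

## Problem sizes and tolerances used in the checks

The validation suite runs the solver-versus-oracle comparison on 500
random 86 × 4 instances (objective agreement within 1e-8), exact recovery
on a 64 × 64 checkerboard (coefficients within 1e-8, residuals ≤ 1e-16),
noisy recovery on 96 × 96 crypt phantoms at 1000 peak counts over three
seeds (per-component r ≥ 0.95, pure-pixel argmax accuracy ≥ 0.99 — the
chain typically achieves r ≥ 0.998 and accuracy 1.0), the calibration
round trip (max relative error < 1e-6 noiseless; < 5 % with a
Poisson-noised 1000-pixel reference well), and photon-budget monotonicity
of pooled RMSE over peak counts {10, 100, 1000, 10000}. These sizes are
desk-scale choices: the generator and pipeline run unchanged at the native
400 × 400 acquisition size.

## Known limitations

* Per-pixel fits are independent; no spatial regularization, sparsity, or
  blind endmember discovery (NMF/VCA) is provided — by design, the basis
  is expert-curated and refined via residual maps.
* Stacks are processed per 2-D plane; depth stacks are independent planes
  with no 3-D registration.
* The red channel's depth-dependent amplitude is handled only by exclusion
  or the free-amplitude option, not modelled.
* The TIFF dialect is package-specific (sidecar-based); an OME-TIFF
  importer is out of scope.
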