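---
title: "Authenticating powdered botanicals from SWIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating powdered botanicals from SWIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsichem)
```

## The problem

Closely related botanical species — here the three medicinal *Echinacea*
species (*E. angustifolia*, *E. purpurea*, *E. pallida*) — are hard to tell
apart once the raw material is milled to powder, and mislabeled commercial
products are a documented problem. Short-wave infrared (SWIR, 920–2514 nm)
hyperspectral imaging measures a full reflectance spectrum at every pixel
of a scene, so a single image of powder wells carries tens of thousands of
spectra that probe the overtone and combination vibrational bands of the
constituents. `hsichem` implements the complete chemometric chain that
turns such an image into a per-sample species-composition report: ENVI
input/output, reference calibration, automated pixel masking, spectral
pretreatments, NIPALS PCA for exploration, and PLS-DA for pixel-wise
classification.

## Signal model and calibration

Raw detector counts are converted to reflectance with the internal dark
and white references,

$$R_{yx\lambda} = \frac{raw_{yx\lambda} - \bar d_\lambda}{\bar w_\lambda - \bar d_\lambda},$$

where $\bar d_\lambda, \bar w_\lambda$ are per-band spatial means of the
reference measurements. The references are averaged to per-band vectors
before use; this suppresses reference noise and treats the illumination as
globally uniform (a per-line variant would suit strongly drifting
pushbroom acquisitions, which we do not model). Reflectance is clipped to
$[10^{-6}, 1.5]$ — the floor keeps the subsequent logarithm finite for
dead pixels, the ceiling tolerates specular pixels brighter than the white
reference — and converted to pseudo-absorbance $A = \log_{10}(1/R)$, which
approximately linearizes the concentration–signal relation and makes
linear mixing assumptions tenable.

## Automated masking

The original interactive practice of lassoing sample pixels in a score
plot is replaced by a deterministic procedure:

1. **Dead pixels**: band-wise variance below $10^{-10}$, any non-finite
   value, or a saturation flag.
2. **Background**: a one-component mean-centered PCA over the remaining
   pixels; since by far the largest variance in such scenes separates the
   sample from the stage, an Otsu threshold on the PC1 score histogram
   splits the image into two groups, and the group with lower mean
   absorbance is called the stage (`background = "high"` flips this for
   absorbing stages).
3. **Edges**: one pass of 4-connected binary erosion of the kept set
   removes mixed sample/stage boundary pixels with minimal area loss.

Masking involves no random numbers, so the mask is a pure function of the
cube.

## Pretreatments

Pixel spectra are processed in a fixed order: wavelength cropping →
scatter correction (SNV or MSC) → optional Savitzky–Golay derivative →
mean centering. Choices worth noting:

* **Cropping at 996 nm.** The short-wave end of the grid (920–996 nm)
  carries no differentiating chemical information and is removed; the cut
  retains strictly the bands above `crop_min_nm`.
* **SNV** standardizes each spectrum to mean 0 and *sample* (n−1) standard
  deviation 1 — the divisor is stated because test oracles depend on it.
  Degenerate (constant) spectra are zero-filled and flagged rather than
  propagated as NaN.
* **MSC** regresses each spectrum on a reference (the training mean by
  default) and returns `(x − intercept)/slope`; near-zero slopes are
  flagged and passed through.
* **Savitzky–Golay derivatives** are computed per band index (the grid is
  nearly uniform at ≈6.25 nm, so per-nm rescaling is an unnecessary
  complication) with defaults window 11, polynomial order 2. Edge points
  are fitted on the truncated window, with the polynomial order reduced
  when the truncated window cannot support it.
* **Mean centering** is fitted on calibration pixels and replayed with the
  stored means on every later pixel; the `PreprocessState` object carries
  all data-dependent state so training and prediction transformations are
  identical by construction.

Scatter correction precedes centering because centering is logically part
of the factor models (PCA/PLS), not of the per-spectrum correction.
Candidate pretreatments are compared by an explicit separation metric
(mean silhouette width of known classes in PCA score space,
`planSeparation()`), not by an automatic optimizer: the plan is a
documented analyst choice.

## NIPALS PCA and PLS-DA

Both factor models use the classical NIPALS formulation with deflation,
the chemometric standard, which also streams naturally over large pixel
counts; full SVD is retained as an independent test oracle. Loadings are
sign-fixed (largest-magnitude element positive) so runs are reproducible.
Convergence is declared when the relative change of the score vector falls
below `1e-9` (500 iterations maximum; non-convergence warns and accepts
the current vector — this occurs only for late, near-degenerate noise
components whose exact rotation is irrelevant).

The exploratory PCA's component count is also cross-validated
(`selectNComponents()`): rows are split into random segments and every
held-out matrix entry is predicted from the row's *other* bands through
the training loadings — for orthonormal loadings this reduces to the
projection residual scaled by 1/(1 − leverage). The distinction matters:
naive projection reconstruction of held-out rows uses the entry itself
and would certify components even on pure noise, whereas the leave-one-
variable-out criterion floors at one component there.

For classification, class membership is one-hot encoded into a dummy Y
matrix and regressed on the spectra with PLS2. The factor count is chosen
from cross-validated $Q^2Y_{cum}(a) = 1 - PRESS(a)/SS(Y)$ with PRESS
pooled over Y columns: pixels are split into 7 random segments (stratified
by class so no fold loses a class; membership drawn once from the seeded
RNG), each segment is left out once, and factors are accepted while the
marginal gain is at least `delta = 0.01`. The "largest factor whose gain
is significant" rule is read sequentially — we stop at the first
non-significant factor — because with noisy gains a global scan could
accept a factor after a long flat stretch, which contradicts the intent of
excluding factors that do not significantly improve $Q^2Y_{cum}$. Both the
gain threshold and the segment count are exposed in the configuration.

Pixels are assigned by the standard dummy-Y window rule with cut-offs 0.5
and 1.5: classes whose predicted value falls inside the window are
candidates; one candidate wins directly, several are resolved by the
largest predicted value (a documented tie-break — the window rule alone
does not define one), and none yields `no_class`, the signal for material
unlike any calibrated class. Per-region composition percentages use kept
(non-background) pixels as the denominator, which is why report rows sum
to 100.

## The synthetic study replica

No image data from the original study are available, so the package ships
a seeded generator whose defaults emulate the study conditions: 256 × 320
pixel scenes on a 256-band 920–2514 nm grid; a calibration scene with 18
wells (3 species × 2 organs × 3 replicates, randomized placement); and a
product scene with 24 wells — 20 simulated commercial products (pure
species, two-species blends, extract-like wells, one multi-herb well with
a minor species fraction) plus 4 authentic controls — with a ground-truth
composition table.

Per pixel, pseudo-absorbance is modeled as

$$a(\lambda) = m\,\big[\mathrm{base}(\lambda) + s\,\mathrm{sig}(\lambda)\big] + b + \varepsilon(\lambda)$$

with lognormal multiplicative scatter $m$ (σ = 0.10, plus a per-material
component), Gaussian baseline offset $b$ (σ = 0.02), i.i.d. band noise
$\varepsilon$ (σ = 0.01), and a lognormal per-pixel *signature strength*
$s$ (σ = 0.28) that scales only the species-discriminating bands. The
signature-strength term models the composition heterogeneity of powders at
sub-millimetre pixel scale; it is what produces the few percent of
weak-signature pixels that fall outside every class window inside
otherwise pure wells — the `no_class` speckle familiar from real
prediction images — while scatter and offset are largely removed by SNV.
Mixing in absorbance is linear (Beer–Lambert-like), keeping the
linearity assumptions of PLS honest. Blend wells are rendered
"particulate" by default: each pixel's material is one component drawn
from the well's weights, as in a powder blend; a "blended" mode with
constant per-pixel weights is also available.

Endmembers are stylized and follow one structural rule: the matrix part
of every plant spectrum (bands at 1195, 1450, 1725, 1930, 2100 nm, plus
leaf-specific bands) depends only on the organ, never on the species —
all species information lives in the signature bands, Gaussian absorption
features concentrated in 1937–2400 nm. Roots carry the signatures at full
depth and leaves at 0.45× (leaf chemistry is less varied); *E. pallida*'s
bands sit farther from the other two species' bands, making it the most
distinct in both organs; and the signatures carry approximately equal
integrated band area. The last two points matter for classification
behavior: with class-independent bases and balanced signatures, a
signature-free spectrum is fundamentally unclassifiable and predicts near
the dummy-Y prior (1/3 per class) rather than inside any class window.
The excipient/extract endmember is exactly such a spectrum — the average
plant matrix with the species chemistry stripped and two faint bands of
its own — mirroring the interpretation that processing alters the
chemistry of extracts, which is why they are predicted `no_class`. The
stage is a spectrally flat, low-absorbance material. No claim of spectral
realism for the actual species is made; the published spectra exist only
as figures.

Synthetic raw counts are produced through smooth synthetic white/dark
gains, and the (noise-free) reference cubes are returned with the scene
so the standard calibration path is exercised. All randomness flows from
one seed; identical seeds give bit-identical scenes.

### What passing tests do and do not show

The replica demonstrates that the *pipeline* is correct and behaves like
the study's workflow under a plausible data-generating model: species
separate in PC1, the discriminating loadings window falls inside
1937–2400 nm, held-out wells classify correctly, extracts report
`no_class`, blends are ranked correctly. It cannot validate instrument
physics, real *Echinacea* spectra, or transferability across instruments
— those require real images.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the full-size 256 × 320
scene for the end-to-end checks (one train/predict cycle takes on the
order of a minute) and compact 96–128-pixel scenes for unit-level checks;
permutation-null checks subsample 150 pixels per class, and silhouette
computations subsample stratified pixels (default cap 600) to keep
distance matrices small. These sizes were chosen so the whole suite runs
comfortably on a laptop while every statistic remains well-resolved.

## Known limitations

* The background rule assumes the stage is the extreme-absorbance group;
  unusual stages need `background = "high"` or a custom mask.
* Dummy-Y PLS-DA gives no calibrated class probabilities and its behavior
  on truly alien material is an extrapolation; `no_class` is a cut-off
  artifact, not an outlier test (SIMCA-style distance-to-model diagnostics
  are out of scope).
* Wavelength grids must match between model and scene; resampling across
  instruments is not provided.
* Mask construction, not watershed splitting, defines regions: touching
  wells are not separated automatically.
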