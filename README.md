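# hsichem

Chemometric authentication of powdered botanical raw material from
short-wave infrared (SWIR) hyperspectral images.

Closely related medicinal species — the motivating case is the three
*Echinacea* species (*E. angustifolia*, *E. purpurea*, *E. pallida*) —
cannot be told apart visually once milled to powder, and mislabeled
commercial products are common. A SWIR hyperspectral image (920–2514 nm)
records a full reflectance spectrum at every pixel, so one image of powder
wells yields tens of thousands of spectra probing the overtone and
combination vibrational bands of the constituents. `hsichem` is aimed at
quality-control analysts and chemometricians who want that analysis as
reproducible code rather than interactive vendor software.

## What it implements

* **ENVI I/O and calibration** — header/data pairs in BSQ/BIL/BIP;
  white/dark reference correction
  `R = (raw − d̄) / (w̄ − d̄)` and pseudo-absorbance `A = log₁₀(1/R)`.
* **Automated masking** — dead-pixel rules, background segmentation by a
  1-component PCA with an Otsu threshold on the PC1 scores, and
  4-connected edge erosion, replacing interactive score-plot lassoing.
* **Pretreatments** — wavelength cropping (≤996 nm removed by default),
  SNV, MSC, Savitzky–Golay derivatives, mean centering, with all fitted
  state replayed identically on prediction pixels.
* **NIPALS PCA** — scores `T`, loadings `P`, per-component and cumulative
  explained variance `R²X`, score images, loadings line plots with the
  maximally discriminating wavelength window, cross-validated component
  selection.
* **NIPALS PLS-DA** — PLS2 against a one-hot class matrix
  `Y ≈ (X − x̄) B + ȳ`, factor count chosen by
  `Q²Y_cum(a) = 1 − PRESS(a)/SS(Y)` from 7 random, class-stratified
  cross-validation segments; pixel classification by the dummy-Y window
  rule (cut-offs 0.5/1.5, `no_class` outside every window); per-region
  composition percentages, label-claim verdicts, external validation.
* **Synthetic study replica** — a seeded generator producing 256 × 320
  ENVI scenes with ground truth: an 18-well calibration scene
  (3 species × 2 organs × 3 replicates) and a 24-well product scene
  (pure species, blends, extract-like wells, multi-herb, authentic
  controls), so the whole pipeline is testable without proprietary data.

See `vignettes/hsi-authentication-methods.Rmd` for the model details and
design rationale.

## Worked example

Train on the simulated calibration scene, validate on the held-out wells,
then quantify the simulated product scene:

```r
library(hsichem)

replica <- makeStudyReplica(seed = 1)
cfg <- runConfig(output_dir = file.path(tempdir(), "run1"))
tr <- runTrain(cfg, scene = replica$calibration)
pr <- runPredict(cfg, tr$archive, scene = replica$products)

tr$model
#> PLSDAModel: 3 classes (E_angustifolia, E_pallida, E_purpurea), 2 factors selected
#>   R2X_cum = 0.8378  R2Y_cum = 0.8796  Q2Y_cum = 0.8795
#>   cross-validation: 7 random segments, seed 1

cat(tr$log, sep = "\n")
#> scene: 256 x 320 pixels, 256 bands
#> mask: 12762 kept, 67574 background, 0 dead, 1584 edge
#> extracted 12762 labeled pixels from 18 regions
#> split: 9 calibration wells (6381 px), 9 test wells (6381 px)
#> PCA: 4 components selected, R2Xcum(3) = 0.9205; window 2020-2314 nm
#> PLS-DA: 2 factors, R2Xcum = 0.8378, R2Ycum = 0.8796, Q2Ycum = 0.8795
#> external validation: 9/9 test wells correct, pixel accuracy 0.973
```

The log reads bottom-up as the paper's workflow: 67 574 stage pixels and
1 584 edge pixels are removed automatically; the discriminating loadings
window (2020–2314 nm) falls in the region where the species signatures
live; the PLS-DA model cross-validates at `Q²Y_cum` 0.88; and all 9
held-out wells are assigned to the correct species with 97.3 % of their
pixels individually correct.

The product report mirrors a species-prediction table — percentages of
kept pixels per class, the dominant prediction, and a verdict against the
label claim:

```r
head(pr$report[, c("region", "class_hint", "E_angustifolia", "E_purpurea",
                   "E_pallida", "no_class", "dominant", "verdict")], 10)
#>  region                class_hint E_angustifolia E_purpurea E_pallida no_class
#>     P01                E_purpurea            0.0      100.0         0        0
#>     P02            E_angustifolia            0.0        0.0         0      100
#>     P03                E_purpurea          100.0        0.0         0        0
#>     P04                E_purpurea            0.0        0.0         0      100
#>     P05 E_angustifolia+E_purpurea           50.1       49.9         0        0
#>     ...
#>        dominant               verdict
#>      E_purpurea                 match
#>        no_class no_authentic_material
#>  E_angustifolia              mismatch
#>        no_class no_authentic_material
#>  E_angustifolia                 match
```

P02/P04 simulate processed extracts: their chemistry lacks the species
signatures, every pixel falls outside all class windows, and the wells
report 100 % `no_class` ("contains little or no authentic raw material").
P03 simulates a mislabeled product — labeled *E. purpurea* but containing
*E. angustifolia* — and the verdict flags the mismatch. P05 is a 50/50
two-species blend recovered as 50.1/49.9.

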