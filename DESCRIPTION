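Package: hsichem
Title: Hyperspectral Imaging Chemometrics for Botanical Raw-Material
    Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for authenticating powdered botanical raw material
    from short-wave infrared (SWIR) hyperspectral images. Provides ENVI
    hypercube input/output, white/dark reference calibration to
    pseudo-absorbance, automated background/dead-pixel/edge masking,
    spectral pretreatments (wavelength cropping, standard normal variate,
    multiplicative scatter correction, Savitzky-Golay derivatives, mean
    centering), NIPALS principal component analysis with score images and
    loadings diagnostics, NIPALS PLS2 discriminant analysis with
    random-segment cross-validation and dummy-Y cut-off classification,
    per-region species-composition reports, and a seeded synthetic-scene
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, EBImage, cluster, yaml, png
Suggests: testthat (>= 3.0.0), signal, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'envi.R'
    'calibrate.R'
    'utils.R'
    'preprocess.R'
    'pca.R'
    'masking.R'
    'plsda.R'
    'synthetic.R'
    'pipeline.R'
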