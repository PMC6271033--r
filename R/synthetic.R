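#' @include plsda.R
NULL

#' Default SWIR wavelength grid
#'
#' 256 bands spanning 920-2514 nm (about 6.25 nm spacing), the grid of a
#' typical SWIR pushbroom imager.
#'
#' @return numeric vector of 256 wavelengths (nm).
#' @export
defaultWavelengthGrid <- function() seq(920, 2514, length.out = 256)

#' Evaluate an endmember's absorbance spectrum
#'
#' An endmember is a stylized pure-material pseudo-absorbance spectrum: a
#' flat baseline plus Gaussian absorption bands.
#'
#' @param spec an endmember spec (element of [defaultEchinaceaLibrary()]):
#'   list with `baseline` and `bands` (data.frame center, width, depth).
#' @param wl wavelength grid (nm).
#' @return numeric absorbance vector along `wl`.
#' @export
endmemberSpectrum <- function(spec, wl) {
  a <- rep(spec$baseline, length(wl))
  b <- spec$bands
  if (!is.null(b) && nrow(b)) {
    for (i in seq_len(nrow(b)))
      a <- a + b$depth[i] * exp(-0.5 * ((wl - b$center[i]) / b$width[i])^2)
  }
  a
}

.bands_df <- function(...) {
  v <- c(...)
  if (is.null(v))
    return(data.frame(center = numeric(0), width = numeric(0),
                      depth = numeric(0), sig = logical(0)))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  data.frame(center = m[, 1], width = m[, 2], depth = m[, 3], sig = FALSE)
}

# split an endmember into its common-matrix part and its species-signature
# part (bands flagged sig = TRUE); the full spectrum is base + signature
.endmember_parts <- function(spec, wl) {
  b <- spec$bands
  base <- spec
  base$bands <- b[!b$sig, , drop = FALSE]
  sigs <- spec
  sigs$baseline <- 0
  sigs$bands <- b[b$sig, , drop = FALSE]
  list(base = endmemberSpectrum(base, wl), signature = endmemberSpectrum(sigs, wl))
}

#' Synthetic endmember library for the three Echinacea species
#'
#' Eight stylized pseudo-absorbance endmembers: root and leaf material of
#' E. angustifolia (class A), E. purpurea (class B) and E. pallida
#' (class C), plus an excipient (a processed-extract/filler material) and
#' the stage (background). All plant endmembers share organ-specific
#' O-H/C-H overtone and combination matrix bands; every bit of species
#' information lives in the signature bands concentrated in the
#' 1937-2400 nm region. Signatures are stronger in roots than in leaves
#' (leaf chemistry is less varied across the species) and E. pallida
#' carries the most distinct signature in both organs. The excipient is
#' the species-free plant matrix (processing strips the discriminating
#' chemistry). The stage is a spectrally flat, low-absorbance
#' (high-reflectance) material, so the default `background = "low"`
#' masking orientation applies.
#'
#' These endmembers are synthetic stand-ins: no claim of spectral realism
#' for the actual species is made.
#'
#' @return named list of endmember specs, each with `name`, `baseline`,
#'   `bands`, `scatter_sigma`, `class` (dummy-Y class label or NA) and
#'   `organ`.
#' @export
defaultEchinaceaLibrary <- function() {
  common <- .bands_df(
    1195, 30, 0.08,
    1450, 45, 0.22,
    1725, 30, 0.06,
    1930, 55, 0.30,
    2100, 60, 0.10)
  leaf_common <- .bands_df(
    1680, 30, 0.05,
    2180, 40, 0.10)
  # The matrix (non-signature) part of every plant endmember depends only
  # on the organ, never on the species: all species information lives in
  # the signature bands. Signatures carry roughly equal total band area,
  # so no class systematically dominates the dummy-Y response of
  # signature-free material. E. pallida's bands sit farther from the other
  # two species' bands (65 nm versus the 45 nm angustifolia/purpurea gap),
  # making it the most distinct species in both organs.
  sig <- list(
    E_angustifolia = .bands_df(2050, 22, 0.30, 2285, 28, 0.20),
    E_purpurea     = .bands_df(2150, 24, 0.30, 2330, 28, 0.20),
    E_pallida      = .bands_df(2220, 20, 0.30, 2395, 22, 0.29))
  mk <- function(name, cls, organ) {
    scale <- if (organ == "root") 1.0 else 0.45
    s <- sig[[cls]]
    s$depth <- s$depth * scale
    s$sig <- TRUE   # species-discriminating bands vary pixel-to-pixel
    bands <- rbind(common, s)
    if (organ == "leaf") bands <- rbind(bands, leaf_common)
    list(name = name, baseline = if (organ == "root") 0.52 else 0.44,
         bands = bands, scatter_sigma = 0.03, class = cls, organ = organ)
  }
  lib <- list(
    ang_root  = mk("ang_root",  "E_angustifolia", "root"),
    ang_leaf  = mk("ang_leaf",  "E_angustifolia", "leaf"),
    purp_root = mk("purp_root", "E_purpurea", "root"),
    purp_leaf = mk("purp_leaf", "E_purpurea", "leaf"),
    pall_root = mk("pall_root", "E_pallida", "root"),
    pall_leaf = mk("pall_leaf", "E_pallida", "leaf"),
    # processed extract / filler: the generic plant matrix (average of the
    # class base spectra) with none of the species-discriminating
    # chemistry (processing strips it), plus two faint bands of its own
    excipient = list(name = "excipient", baseline = 0.47,
                     bands = rbind(within(common, depth <- depth * 0.95),
                                   within(leaf_common, depth <- depth * 0.5),
                                   .bands_df(1560, 26, 0.06, 1820, 24, 0.05)),
                     scatter_sigma = 0.03, class = NA_character_,
                     organ = NA_character_),
    stage = list(name = "stage", baseline = 0.06, bands = .bands_df(),
                 scatter_sigma = 0.01, class = NA_character_,
                 organ = NA_character_))
  lib
}

#' Default scene noise levels
#'
#' Four noise components, all in pseudo-absorbance units:
#' `sigma_m` — lognormal sigma of the per-pixel multiplicative scatter
#' (particle-size effects); `sigma_a` — SD of the per-pixel additive
#' baseline offset; `sigma_e` — SD of i.i.d. band-wise detector noise;
#' `sigma_s` — lognormal sigma of the per-pixel species-signature strength
#' (composition heterogeneity of powdered plant material at sub-millimetre
#' pixel scale; applies to the endmember bands flagged as discriminating).
#' Levels are chosen to emulate powdered botanical material imaged in
#' SWIR: species remain clearly separable while a small percentage of
#' weak-signature pixels falls outside the class windows.
#'
#' @return list(sigma_m, sigma_a, sigma_e, sigma_s).
#' @export
defaultSceneNoise <- function()
  list(sigma_m = 0.10, sigma_a = 0.02, sigma_e = 0.01, sigma_s = 0.28)

#' Specify a synthetic scene
#'
#' @param wells list of wells; each a list with `cy`, `cx`, `r` (0-based
#'   disk center and radius in pixels), `label`, `class_hint` (claimed
#'   composition, e.g. `"E_purpurea"` or `"E_angustifolia+E_purpurea"`),
#'   and `material`: a named numeric vector of endmember weights (weights
#'   sum to at most 1; any remainder is excipient). A single endmember name
#'   is shorthand for weight 1.
#' @param shape image shape `c(lines, samples)` (default 256 x 320).
#' @param wavelengths band grid (default [defaultWavelengthGrid()]).
#' @param noise list(sigma_m, sigma_a, sigma_e); default
#'   [defaultSceneNoise()].
#' @param mixing `"particulate"` (each pixel's material is one component
#'   drawn from the well's weights — powder blends at sub-millimetre pixel
#'   scale) or `"blended"` (every pixel carries the weighted spectrum).
#' @param seed RNG seed for all randomness in the scene.
#' @return A scene spec list for [renderScene()].
#' @export
sceneSpec <- function(wells, shape = c(256, 320),
                      wavelengths = defaultWavelengthGrid(),
                      noise = defaultSceneNoise(),
                      mixing = c("particulate", "blended"), seed = 1) {
  mixing <- match.arg(mixing)
  wells <- lapply(wells, function(w) {
    if (is.character(w$material)) {
      mat <- stats::setNames(1, w$material)
      w$material <- mat
    }
    if (any(w$material < 0) || sum(w$material) > 1 + 1e-9)
      stop("well '", w$label, "': weights must be non-negative and sum <= 1")
    w
  })
  list(shape = shape, wavelengths = wavelengths, wells = wells,
       noise = noise, mixing = mixing, seed = seed)
}

.check_well_overlap <- function(wells) {
  n <- length(wells)
  if (n < 2) return(invisible())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    di <- sqrt((wells[[i]]$cy - wells[[j]]$cy)^2 + (wells[[i]]$cx - wells[[j]]$cx)^2)
    if (di <= wells[[i]]$r + wells[[j]]$r)
      stop("wells '", wells[[i]]$label, "' and '", wells[[j]]$label, "' overlap")
  }
}

#' Render a synthetic scene to a raw hypercube with ground truth
#'
#' Per pixel, the pseudo-absorbance spectrum is
#' `a(lambda) = m * sum_i w_i [base_i(lambda) + s * signature_i(lambda)] +
#' offset + eps(lambda)` with `m` lognormal (multiplicative scatter), `s`
#' lognormal (per-pixel species-signature strength, the composition
#' heterogeneity of powdered material), `offset` Gaussian (additive
#' baseline) and `eps` i.i.d. Gaussian band noise; `base + signature` is
#' the endmember spectrum. The absorbance scene is
#' converted to reflectance `10^(-a)` and then to raw detector counts
#' through synthetic white/dark references with known smooth gains; the
#' (noise-free) reference cubes are returned alongside so the standard
#' calibration path can be exercised. Identical seeds give identical
#' output.
#'
#' @param spec a scene spec from [sceneSpec()].
#' @param library endmember library (default [defaultEchinaceaLibrary()]).
#' @return list: `raw` (raw-counts [Hypercube-class]), `refs`
#'   ([ReferencePair-class]), `truth` (list: `layout` [RegionLayout-class]
#'   of the wells, `classMap` character matrix of per-pixel true class —
#'   class labels, `"excipient"`, or `"stage"` —, `absorbance` the
#'   noise-free class spectra are recoverable from the library, and
#'   `composition` data.frame of per-well true class weights).
#' @export
renderScene <- function(spec, library = defaultEchinaceaLibrary()) {
  .check_well_overlap(spec$wells)
  nl <- spec$shape[1]; ns <- spec$shape[2]
  wl <- spec$wavelengths
  nb <- length(wl)
  npix <- nl * ns
  spectra <- lapply(library, endmemberSpectrum, wl = wl)
  parts <- lapply(library, .endmember_parts, wl = wl)
  emClass <- vapply(library, function(e)
    if (is.na(e$class)) e$name else e$class, character(1))

  classMap <- matrix("stage", nl, ns)
  E <- matrix(parts$stage$base, npix, nb, byrow = TRUE)
  Esig <- matrix(0, npix, nb)
  sigmaEM <- rep(library$stage$scatter_sigma, npix)

  classes <- c("E_angustifolia", "E_purpurea", "E_pallida")
  compRows <- list()

  out <- withSeed(spec$seed, {
    for (w in spec$wells) {
      memb <- which(.region_membership("disk", c(w$cy, w$cx, w$r), c(nl, ns)))
      wts <- w$material
      if (sum(wts) < 1 - 1e-9)
        wts <- c(wts, excipient = 1 - sum(wts))
      if (!all(names(wts) %in% names(library)))
        stop("unknown endmember(s): ",
             paste(setdiff(names(wts), names(library)), collapse = ", "))
      if (spec$mixing == "particulate" && length(wts) > 1) {
        comp <- sample(names(wts), length(memb), replace = TRUE, prob = wts)
        for (nm in unique(comp)) {
          ii <- memb[comp == nm]
          E[ii, ] <- matrix(parts[[nm]]$base, length(ii), nb, byrow = TRUE)
          Esig[ii, ] <- matrix(parts[[nm]]$signature, length(ii), nb, byrow = TRUE)
          classMap[ii] <- emClass[[nm]]
          sigmaEM[ii] <- library[[nm]]$scatter_sigma
        }
      } else {
        mixbase <- Reduce(`+`, Map(function(nm, wt) wt * parts[[nm]]$base,
                                   names(wts), wts))
        mixsig <- Reduce(`+`, Map(function(nm, wt) wt * parts[[nm]]$signature,
                                  names(wts), wts))
        E[memb, ] <- matrix(mixbase, length(memb), nb, byrow = TRUE)
        Esig[memb, ] <- matrix(mixsig, length(memb), nb, byrow = TRUE)
        classMap[memb] <- emClass[[names(wts)[which.max(wts)]]]
        sigmaEM[memb] <- max(vapply(names(wts),
                                    function(nm) library[[nm]]$scatter_sigma, 1))
      }
      wtsByClass <- stats::setNames(numeric(4), c(classes, "excipient"))
      for (nm in names(wts))
        wtsByClass[emClass[[nm]]] <- wtsByClass[emClass[[nm]]] + wts[[nm]]
      compRows[[w$label]] <- data.frame(region = w$label,
                                        class_hint = as.character(
                                          w$class_hint %||% NA_character_),
                                        t(wtsByClass), stringsAsFactors = FALSE)
    }
    nz <- spec$noise
    sigma_s <- nz$sigma_s %||% 0
    m <- if (nz$sigma_m > 0)
      exp(stats::rnorm(npix, 0, 1) * sqrt(nz$sigma_m^2 + sigmaEM^2))
      else rep(1, npix)
    s <- if (sigma_s > 0) exp(stats::rnorm(npix, 0, sigma_s)) else rep(1, npix)
    offset <- stats::rnorm(npix, 0, nz$sigma_a)
    A <- (E + Esig * s) * m + offset
    if (nz$sigma_e > 0) A <- A + stats::rnorm(length(A), 0, nz$sigma_e)
    A
  })

  R <- 10^(-out)
  white <- 11000 - 4000 * (wl - wl[1]) / (wl[nb] - wl[1])
  dark <- rep(500, nb)
  raw <- sweep(R, 2, white - dark, "*")
  raw <- sweep(raw, 2, dark, "+")

  refCube <- function(v) Hypercube(
    array(rep(v, each = 8L * ns), c(8L, ns, nb)), wl, "raw_counts")
  layout <- RegionLayout(
    label = vapply(spec$wells, `[[`, character(1), "label"),
    class_hint = vapply(spec$wells, function(w)
                          as.character(w$class_hint %||% NA_character_),
                        character(1)),
    shape = "disk",
    params = lapply(spec$wells, function(w) c(w$cy, w$cx, w$r)))
  composition <- do.call(rbind, c(compRows, make.row.names = FALSE))

  list(raw = Hypercube(array(raw, c(nl, ns, nb)), wl, "raw_counts",
                       metadata = list(description = "synthetic scene")),
       refs = ReferencePair(dark = refCube(dark), white = refCube(white)),
       truth = list(layout = layout, classMap = classMap,
                    composition = composition))
}

# grid-with-jitter well placement; deterministic given the RNG state
.place_wells <- function(nrows, ncols, shape, r, jitter) {
  ys <- round(seq(r + 10, shape[1] - r - 10, length.out = nrows))
  xs <- round(seq(r + 10, shape[2] - r - 10, length.out = ncols))
  pos <- expand.grid(cy = ys, cx = xs)
  pos$cy <- pos$cy + sample(-jitter:jitter, nrow(pos), replace = TRUE)
  pos$cx <- pos$cx + sample(-jitter:jitter, nrow(pos), replace = TRUE)
  pos
}

#' Build the two-scene study replica
#'
#' Scene 1 (calibration/test): 18 wells — root and leaf powder of the three
#' species, three replicates each — placed in randomized positions on the
#' stage. Scene 2 (products): 24 wells — 20 "commercial products" (pure
#' species, two-species blends, extract-like pure-excipient wells and a
#' multi-herb well with a minor species fraction) plus 4 authentic
#' raw-material controls — with a ground-truth composition table.
#'
#' @param seed master seed; all placement, material draws and noise derive
#'   from it.
#' @param noise scene noise (default [defaultSceneNoise()]).
#' @param well_radius disk radius in pixels (default 16).
#' @return list with `calibration` and `products`, each a [renderScene()]
#'   result, plus `library`.
#' @export
makeStudyReplica <- function(seed = 1, noise = defaultSceneNoise(),
                             well_radius = 16) {
  lib <- defaultEchinaceaLibrary()
  shape <- c(256L, 320L)
  A <- "E_angustifolia"; B <- "E_purpurea"; C <- "E_pallida"

  mats <- c("ang_root", "ang_leaf", "purp_root", "purp_leaf",
            "pall_root", "pall_leaf")
  cal_wells <- withSeed((seed * 7 + 1) %% 2147483647, {
    pos <- .place_wells(3, 6, shape, well_radius, 6)
    ord <- sample(18L)  # randomized placement of the 18 samples
    slots <- rep(mats, each = 3)[ord]
    reps <- as.vector(vapply(mats, function(m) seq_len(3), integer(3)))[ord]
    lapply(seq_len(18), function(i) {
      em <- lib[[slots[i]]]
      list(cy = pos$cy[i], cx = pos$cx[i], r = well_radius,
           label = sprintf("%s_%d", slots[i], reps[i]),
           class_hint = em$class, material = slots[i], organ = em$organ)
    })
  })

  pr <- function(mat) stats::setNames(1, mat)
  products <- list(
    list("P01", B,                  pr("purp_root")),
    list("P02", A,                  pr("excipient")),
    list("P03", B,                  pr("ang_root")),
    list("P04", B,                  pr("excipient")),
    list("P05", paste(A, B, sep = "+"), c(ang_root = 0.5, purp_root = 0.5)),
    list("P06", paste(A, B, sep = "+"), pr("ang_root")),
    list("P07", B,                  pr("excipient")),
    list("P08", B,                  pr("excipient")),
    list("P09", C,                  pr("purp_root")),
    list("P10", paste(A, B, sep = "+"), c(ang_root = 0.6, purp_root = 0.4)),
    list("P11", A,                  pr("ang_root")),
    list("P12", B,                  pr("purp_leaf")),
    list("P13", paste(C, B, sep = "+"), c(purp_leaf = 0.5, pall_leaf = 0.5)),
    list("P14", B,                  pr("purp_root")),
    list("P15", A,                  pr("excipient")),
    list("P16", B,                  pr("ang_leaf")),
    list("P17", B,                  pr("purp_root")),
    list("P18", paste(A, B, C, sep = "+"), pr("purp_leaf")),
    list("P19", B,                  pr("purp_leaf")),
    list("P20", paste(A, B, C, sep = "+"), c(purp_root = 0.25)),  # rest excipient
    list("P21", B,                  pr("purp_leaf")),
    list("P22", A,                  pr("ang_root")),
    list("P23", B,                  pr("purp_root")),
    list("P24", A,                  pr("ang_leaf")))
  prod_wells <- withSeed((seed * 7 + 2) %% 2147483647, {
    pos <- .place_wells(4, 6, shape, well_radius, 5)
    lapply(seq_along(products), function(i) {
      p <- products[[i]]
      list(cy = pos$cy[i], cx = pos$cx[i], r = well_radius,
           label = p[[1]], class_hint = p[[2]], material = p[[3]])
    })
  })

  cal_scene <- renderScene(sceneSpec(cal_wells, shape = shape, noise = noise,
                                     seed = (seed * 7 + 3) %% 2147483647), lib)
  # record organs in the calibration composition table
  cal_scene$truth$composition$organ <-
    vapply(cal_wells, function(w) w$organ, character(1))[
      match(cal_scene$truth$composition$region,
            vapply(cal_wells, `[[`, character(1), "label"))]
  prod_scene <- renderScene(sceneSpec(prod_wells, shape = shape, noise = noise,
                                      seed = (seed * 7 + 4) %% 2147483647), lib)
  list(calibration = cal_scene, products = prod_scene, library = lib)
}
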