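#' @import methods
NULL

.SIGNAL_KINDS <- c("raw_counts", "reflectance", "pseudo_absorbance")

#' Hypercube: a hyperspectral image cube
#'
#' Container for a hyperspectral image: a 3-D numeric array indexed
#' (line, sample, band) together with the band-center wavelengths in
#' nanometres and a tag saying what physical quantity the values are.
#'
#' The in-memory layout is always (line, sample, band); file interleave
#' (BIL/BIP/BSQ) is purely an I/O concern handled by [readENVI()] and
#' [writeENVI()].
#'
#' @slot data numeric 3-D array, dimensions lines x samples x bands.
#' @slot wavelengths strictly increasing numeric vector of band centers (nm).
#' @slot signalKind one of `"raw_counts"`, `"reflectance"`,
#'   `"pseudo_absorbance"`.
#' @slot metadata free-form named list (acquisition description etc.).
#' @slot rMax upper bound tolerated for reflectance values (default 1.5,
#'   allowing specular pixels above the white reference).
#'
#' @export
setClass("Hypercube",
  representation(
    data = "array",
    wavelengths = "numeric",
    signalKind = "character",
    metadata = "list",
    rMax = "numeric"
  ),
  prototype(signalKind = "raw_counts", metadata = list(), rMax = 1.5)
)

setValidity("Hypercube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (lines, samples, bands)")
  if (d[1] < 1L || d[2] < 1L) return("spatial dimensions must be positive")
  wl <- object@wavelengths
  if (d[3] != length(wl))
    return(sprintf("band dimension (%d) != length(wavelengths) (%d)", d[3], length(wl)))
  if (!all(is.finite(wl))) return("wavelengths must be finite")
  if (length(wl) > 1L && any(diff(wl) <= 0)) return("wavelengths must be strictly increasing")
  if (!object@signalKind %in% .SIGNAL_KINDS)
    return(sprintf("signalKind must be one of %s", paste(.SIGNAL_KINDS, collapse = ", ")))
  if (object@signalKind == "reflectance") {
    rng <- range(object@data)
    if (!all(is.finite(rng))) return("reflectance values must be finite")
    if (rng[1] < 0 || rng[2] > object@rMax + 1e-12)
      return(sprintf("reflectance values must lie in [0, %g]", object@rMax))
  }
  TRUE
})

#' Construct a Hypercube
#'
#' @param data numeric 3-D array (lines x samples x bands).
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, one per band.
#' @param signalKind what the values are: `"raw_counts"` (detector counts),
#'   `"reflectance"`, or `"pseudo_absorbance"` (log10(1/R)).
#' @param metadata named list of free-form metadata.
#' @param rMax tolerated reflectance ceiling (see class docs).
#' @return A [Hypercube-class] object.
#' @examples
#' cube <- Hypercube(array(runif(2 * 3 * 4), c(2, 3, 4)),
#'                   wavelengths = c(1000, 1100, 1200, 1300),
#'                   signalKind = "reflectance")
#' dim(cube)
#' @export
Hypercube <- function(data, wavelengths, signalKind = "raw_counts",
                      metadata = list(), rMax = 1.5) {
  new("Hypercube", data = data, wavelengths = as.numeric(wavelengths),
      signalKind = signalKind, metadata = metadata, rMax = rMax)
}

#' ReferencePair: dark and white calibration references
#'
#' Holds the internal dark and white reference measurements used to convert
#' raw detector counts to reflectance. Each reference may be a raw-counts
#' [Hypercube-class] (it is averaged over its spatial extent to a per-band
#' vector before use) or directly a per-band numeric vector.
#'
#' @slot dark dark reference (Hypercube or numeric vector).
#' @slot white white reference (Hypercube or numeric vector).
#' @export
setClass("ReferencePair", representation(dark = "ANY", white = "ANY"))

setValidity("ReferencePair", function(object) {
  ok <- function(x) is(x, "Hypercube") || is.numeric(x)
  if (!ok(object@dark)) return("dark must be a Hypercube or numeric vector")
  if (!ok(object@white)) return("white must be a Hypercube or numeric vector")
  TRUE
})

#' @param dark,white dark / white reference: raw-counts Hypercube or
#'   per-band numeric vector.
#' @return A `ReferencePair` object.
#' @rdname ReferencePair-class
#' @export
ReferencePair <- function(dark, white) new("ReferencePair", dark = dark, white = white)

#' RegionLayout: labeled sample regions on the image
#'
#' Ties pixel coordinates to sample identities: each region is a rectangle
#' or a disk with a unique label and an optional class hint (the species or
#' species/organ code claimed for the material in that region).
#'
#' Coordinates follow the layout convention of the file format: 0-based,
#' with rectangles half-open (`y0 <= y < y1`, `x0 <= x < x1`) and disks
#' including pixels whose center distance from (`cy`,`cx`) is `<= r`.
#'
#' @slot regions data.frame with columns `label`, `class_hint`, `shape`
#'   (`"rect"` or `"disk"`) and numeric `p1..p4` (rect: y0,x0,y1,x1;
#'   disk: cy,cx,r with p4 = NA).
#' @export
setClass("RegionLayout", representation(regions = "data.frame"))

setValidity("RegionLayout", function(object) {
  r <- object@regions
  need <- c("label", "class_hint", "shape", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(r))) return("regions must have columns label, class_hint, shape, p1..p4")
  if (anyDuplicated(r$label)) return("region labels must be unique")
  if (!all(r$shape %in% c("rect", "disk"))) return("shape must be 'rect' or 'disk'")
  bad <- r$shape == "rect" & (r$p3 <= r$p1 | r$p4 <= r$p2)
  if (any(bad)) return("rectangles must satisfy y1 > y0 and x1 > x0")
  if (any(r$shape == "disk" & r$p3 < 0)) return("disk radius must be >= 0")
  TRUE
})

#' Construct a RegionLayout
#'
#' @param label character vector of unique region labels.
#' @param class_hint character vector (NA allowed) of claimed class codes.
#' @param shape `"rect"` or `"disk"` per region.
#' @param params list of numeric vectors: `c(y0, x0, y1, x1)` for rect
#'   (0-based, half-open) or `c(cy, cx, r)` for disk.
#' @return A [RegionLayout-class] object.
#' @export
RegionLayout <- function(label, class_hint = NA_character_, shape, params) {
  n <- length(label)
  class_hint <- rep_len(as.character(class_hint), n)
  shape <- rep_len(shape, n)
  pm <- t(vapply(params, function(p) c(p, rep(NA_real_, 4 - length(p)))[1:4], numeric(4)))
  df <- data.frame(label = as.character(label), class_hint = class_hint,
                   shape = shape, p1 = pm[, 1], p2 = pm[, 2], p3 = pm[, 3],
                   p4 = pm[, 4], stringsAsFactors = FALSE)
  new("RegionLayout", regions = df)
}

#' PixelMask: kept/removed pixels with removal provenance
#'
#' Boolean foreground mask over the spatial grid plus a per-pixel record of
#' why removed pixels were removed (`"kept"`, `"background"`, `"dead"`,
#' `"edge"`).
#'
#' @slot keep logical matrix (lines x samples); TRUE = analyse this pixel.
#' @slot provenance character matrix, same shape; `"kept"` exactly where
#'   `keep` is TRUE.
#' @export
setClass("PixelMask", representation(keep = "matrix", provenance = "matrix"))

setValidity("PixelMask", function(object) {
  if (!is.logical(object@keep)) return("keep must be a logical matrix")
  if (!identical(dim(object@keep), dim(object@provenance)))
    return("keep and provenance must have identical dimensions")
  if (!all(object@provenance %in% c("kept", "background", "dead", "edge")))
    return("provenance values must be kept/background/dead/edge")
  if (!identical(as.vector(object@keep), as.vector(object@provenance == "kept")))
    return("keep must be TRUE exactly where provenance == 'kept'")
  if (mean(object@keep) < 0.01)
    return("fewer than 1% of pixels kept; masking failed")
  TRUE
})

#' @param keep logical matrix of kept pixels.
#' @param provenance character matrix of removal reasons; defaults to
#'   `"kept"`/`"background"` derived from `keep`.
#' @return A `PixelMask` object.
#' @rdname PixelMask-class
#' @export
PixelMask <- function(keep, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- matrix(ifelse(keep, "kept", "background"), nrow(keep), ncol(keep))
  }
  new("PixelMask", keep = keep, provenance = provenance)
}

#' PreprocessPlan: ordered spectral pretreatment recipe
#'
#' An ordered list of pretreatment steps applied to pixel spectra before
#' modeling. Allowed steps: `crop_wavelengths(min_nm)`, `snv`,
#' `msc(reference)`, `savgol_derivative(window, polyorder, deriv)`,
#' `mean_center`. Cropping, if present, must come first; mean centering,
#' if present, last.
#'
#' @slot steps list of step descriptors, each a named list with a `type`
#'   element and step parameters.
#' @export
setClass("PreprocessPlan", representation(steps = "list"))

.PLAN_STEPS <- c("crop_wavelengths", "snv", "msc", "savgol_derivative", "mean_center")

setValidity("PreprocessPlan", function(object) {
  st <- object@steps
  types <- vapply(st, function(s) s$type %||% "", character(1))
  if (!all(types %in% .PLAN_STEPS))
    return(sprintf("unknown step type(s): %s", paste(setdiff(types, .PLAN_STEPS), collapse = ", ")))
  if ("crop_wavelengths" %in% types && types[1] != "crop_wavelengths")
    return("crop_wavelengths, if present, must be the first step")
  if ("mean_center" %in% types && types[length(types)] != "mean_center")
    return("mean_center, if present, must be the last step")
  for (s in st[types == "savgol_derivative"]) {
    if (s$window %% 2 == 0) return("savgol window must be odd")
    if (s$polyorder >= s$window) return("savgol polyorder must be < window")
    if (!s$deriv %in% c(1, 2)) return("savgol deriv must be 1 or 2")
  }
  TRUE
})

#' Build a preprocessing plan
#'
#' Convenience constructor for the usual pipeline order:
#' crop -> scatter correction -> optional derivative -> mean centering.
#'
#' @param crop_min_nm if non-NULL, drop all bands with wavelength
#'   `<= crop_min_nm` first (default 996 nm removes the uninformative
#'   short-wave end of the SWIR grid).
#' @param scatter `"snv"`, `"msc"` or `"none"`.
#' @param derivative NULL or a list `list(window=, polyorder=, deriv=)` for a
#'   Savitzky-Golay derivative.
#' @param mean_center append a mean-centering step (default TRUE).
#' @return A [PreprocessPlan-class].
#' @examples
#' preprocessPlan(crop_min_nm = 996, scatter = "snv")
#' @export
preprocessPlan <- function(crop_min_nm = 996, scatter = c("snv", "msc", "none"),
                           derivative = NULL, mean_center = TRUE) {
  scatter <- match.arg(scatter)
  steps <- list()
  if (!is.null(crop_min_nm))
    steps <- c(steps, list(list(type = "crop_wavelengths", min_nm = crop_min_nm)))
  if (scatter == "snv") steps <- c(steps, list(list(type = "snv")))
  if (scatter == "msc") steps <- c(steps, list(list(type = "msc", reference = "mean")))
  if (!is.null(derivative))
    steps <- c(steps, list(c(list(type = "savgol_derivative"), derivative)))
  if (mean_center) steps <- c(steps, list(list(type = "mean_center")))
  new("PreprocessPlan", steps = steps)
}

#' PreprocessState: a fitted preprocessing pipeline
#'
#' Stores everything learned from the training pixels (retained band
#' indices, MSC reference spectrum, column means) so that exactly the same
#' transformation can be replayed on prediction pixels.
#'
#' @slot plan the [PreprocessPlan-class] that was fitted.
#' @slot wavelengthsIn input wavelength grid.
#' @slot keepBands integer indices of bands retained by cropping.
#' @slot mscReference numeric reference spectrum (length 0 if no MSC step).
#' @slot columnMeans stored column means (length 0 if no mean_center step).
#' @export
setClass("PreprocessState",
  representation(plan = "PreprocessPlan", wavelengthsIn = "numeric",
                 keepBands = "integer", mscReference = "numeric",
                 columnMeans = "numeric"))

#' PCAModel: NIPALS principal component analysis model
#'
#' @slot center band-wise mean spectrum subtracted before decomposition.
#' @slot loadings bands x A matrix, columns unit-norm.
#' @slot scores n x A matrix of training-pixel scores.
#' @slot r2x per-component fraction of (centered) X variance explained.
#' @slot r2xCum cumulative fractions.
#' @slot totalSS total centered sum of squares of the training matrix.
#' @slot wavelengths band wavelengths (nm) for plotting; may be empty.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix", scores = "matrix",
                 r2x = "numeric", r2xCum = "numeric", totalSS = "numeric",
                 wavelengths = "numeric"))

setValidity("PCAModel", function(object) {
  P <- object@loadings
  A <- ncol(P)
  if (ncol(object@scores) != A) return("scores and loadings disagree on component count")
  if (length(object@r2x) != A || length(object@r2xCum) != A)
    return("r2x vectors must have one entry per component")
  G <- crossprod(P)
  if (max(abs(G - diag(A))) > 1e-8) return("loadings columns must be orthonormal")
  if (any(diff(object@r2xCum) < -1e-10)) return("r2xCum must be non-decreasing")
  if (any(object@r2xCum > 1 + 1e-8)) return("r2xCum must not exceed 1")
  TRUE
})

#' ScoreImage: spatial map of one component's scores
#'
#' @slot values numeric matrix (lines x samples); NA at removed pixels.
#' @slot component which component the map shows.
#' @slot bounds symmetric color-scale bounds `c(lo, hi)`.
#' @export
setClass("ScoreImage",
  representation(values = "matrix", component = "integer", bounds = "numeric"))

#' PLSDAModel: NIPALS PLS2 discriminant model
#'
#' Partial least squares regression of spectra against a one-hot dummy class
#' matrix, with per-factor cumulative R2X, R2Y and cross-validated Q2Y.
#'
#' @slot classes ordered class labels (the codebook).
#' @slot xMean,yMean column means of X and dummy Y.
#' @slot weights bands x A X-weight matrix W.
#' @slot xLoadings bands x A loading matrix P.
#' @slot yLoadings classes x A Y-loading matrix Q.
#' @slot scores n x A training score matrix T.
#' @slot coefficients bands x classes regression coefficient matrix B so
#'   that Yhat = (X - xMean) B + yMean.
#' @slot nFactors selected number of factors A.
#' @slot r2xCum,r2yCum,q2yCum cumulative statistics per candidate factor
#'   (length = number of candidate factors evaluated; the selected model
#'   uses the first `nFactors` of them).
#' @slot cvSpec list(nSegments, seed) describing the cross-validation.
#' @export
setClass("PLSDAModel",
  representation(classes = "character", xMean = "numeric", yMean = "numeric",
                 weights = "matrix", xLoadings = "matrix", yLoadings = "matrix",
                 scores = "matrix", coefficients = "matrix", nFactors = "integer",
                 r2xCum = "numeric", r2yCum = "numeric", q2yCum = "numeric",
                 cvSpec = "list"))

setValidity("PLSDAModel", function(object) {
  if (length(object@classes) < 2) return("need at least 2 classes")
  if (anyDuplicated(object@classes)) return("class labels must be unique")
  A <- object@nFactors
  if (ncol(object@weights) < A) return("fewer weight columns than nFactors")
  nEval <- length(object@q2yCum)
  if (any(object@q2yCum > object@r2yCum[seq_len(nEval)] + 1e-9))
    return("q2yCum must not exceed r2yCum")
  TRUE
})

#' ClassPredictionImage: per-pixel class assignments
#'
#' @slot classes class labels of the model.
#' @slot labels integer matrix (lines x samples): NA = masked, 0 = no_class,
#'   k = k-th class.
#' @slot yhat 3-D array (lines x samples x classes) of continuous predicted
#'   dummy-Y values (NA at masked pixels).
#' @export
setClass("ClassPredictionImage",
  representation(classes = "character", labels = "matrix", yhat = "array"))

setValidity("ClassPredictionImage", function(object) {
  lv <- object@labels
  if (any(!is.na(lv) & (lv < 0 | lv > length(object@classes))))
    return("labels must be NA, 0 (no_class) or a class index")
  TRUE
})
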