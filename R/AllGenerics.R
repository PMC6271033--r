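#' @include AllClasses.R
NULL

#' Band-center wavelengths
#' @param x an object with a wavelength grid.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Signal kind of a cube
#' @param x a [Hypercube-class].
#' @return `"raw_counts"`, `"reflectance"` or `"pseudo_absorbance"`.
#' @export
setGeneric("signalKind", function(x) standardGeneric("signalKind"))

#' Cube data array
#' @param x a [Hypercube-class].
#' @return the (lines x samples x bands) array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' Kept-pixel matrix of a mask
#' @param x a [PixelMask-class].
#' @return logical matrix.
#' @export
setGeneric("keepMatrix", function(x) standardGeneric("keepMatrix"))

#' Removal provenance of a mask
#' @param x a [PixelMask-class].
#' @return character matrix of reasons.
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' Region table of a layout
#' @param x a [RegionLayout-class].
#' @return data.frame of regions.
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' Model scores
#' @param x a fitted model.
#' @return score matrix T.
#' @export
setGeneric("modelScores", function(x) standardGeneric("modelScores"))

#' Model loadings
#' @param x a fitted model.
#' @return loading matrix P.
#' @export
setGeneric("modelLoadings", function(x) standardGeneric("modelLoadings"))

#' Number of components / factors
#' @param x a fitted model.
#' @return integer.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Cumulative explained X variance
#' @param x a fitted model.
#' @return numeric vector of cumulative fractions.
#' @export
setGeneric("r2xCum", function(x) standardGeneric("r2xCum"))

#' Cumulative cross-validated Y variance (Q2Y)
#' @param x a [PLSDAModel-class].
#' @return numeric vector.
#' @export
setGeneric("q2yCum", function(x) standardGeneric("q2yCum"))
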