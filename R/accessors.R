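#' @include AllGenerics.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn Hypercube wavelength grid (nm).
#' @param x a Hypercube.
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' @describeIn Hypercube signal kind.
#' @export
setMethod("signalKind", "Hypercube", function(x) x@signalKind)

#' @describeIn Hypercube the raw data array.
#' @export
setMethod("cubeData", "Hypercube", function(x) x@data)

#' @describeIn Hypercube dimensions (lines, samples, bands).
#' @export
setMethod("dim", "Hypercube", function(x) dim(x@data))

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube: %d lines x %d samples x %d bands [%s]\n",
              d[1], d[2], d[3], object@signalKind))
  cat(sprintf("  wavelengths: %.1f-%.1f nm\n",
              min(object@wavelengths), max(object@wavelengths)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' @describeIn PixelMask kept-pixel matrix.
#' @param x a PixelMask.
#' @export
setMethod("keepMatrix", "PixelMask", function(x) x@keep)

#' @describeIn PixelMask removal provenance matrix.
#' @export
setMethod("maskProvenance", "PixelMask", function(x) x@provenance)

setMethod("show", "PixelMask", function(object) {
  tab <- table(factor(object@provenance,
                      levels = c("kept", "background", "dead", "edge")))
  cat(sprintf("PixelMask: %d x %d, %.1f%% kept\n", nrow(object@keep),
              ncol(object@keep), 100 * mean(object@keep)))
  print(tab)
})

#' @describeIn RegionLayout region table.
#' @param x a RegionLayout.
#' @export
setMethod("regionTable", "RegionLayout", function(x) x@regions)

setMethod("show", "RegionLayout", function(object) {
  cat(sprintf("RegionLayout with %d regions (%d rect, %d disk)\n",
              nrow(object@regions), sum(object@regions$shape == "rect"),
              sum(object@regions$shape == "disk")))
})

setMethod("length", "RegionLayout", function(x) nrow(x@regions))

#' @describeIn PCAModel score matrix.
#' @param x a PCAModel.
#' @export
setMethod("modelScores", "PCAModel", function(x) x@scores)

#' @describeIn PCAModel loading matrix.
#' @export
setMethod("modelLoadings", "PCAModel", function(x) x@loadings)

#' @describeIn PCAModel number of components.
#' @export
setMethod("nComponents", "PCAModel", function(x) ncol(x@loadings))

#' @describeIn PCAModel cumulative explained variance.
#' @export
setMethod("r2xCum", "PCAModel", function(x) x@r2xCum)

setMethod("show", "PCAModel", function(object) {
  A <- ncol(object@loadings)
  cat(sprintf("PCAModel: %d components over %d bands (n = %d pixels)\n",
              A, nrow(object@loadings), nrow(object@scores)))
  cat("  R2X per component:", paste(sprintf("%.3f", object@r2x), collapse = " "), "\n")
  cat(sprintf("  R2X cumulative:  %.4f\n", object@r2xCum[A]))
})

#' @describeIn PLSDAModel score matrix.
#' @param x a PLSDAModel.
#' @export
setMethod("modelScores", "PLSDAModel", function(x) x@scores)

#' @describeIn PLSDAModel X-loading matrix.
#' @export
setMethod("modelLoadings", "PLSDAModel", function(x) x@xLoadings)

#' @describeIn PLSDAModel selected number of factors.
#' @export
setMethod("nComponents", "PLSDAModel", function(x) x@nFactors)

#' @describeIn PLSDAModel cumulative R2X per factor.
#' @export
setMethod("r2xCum", "PLSDAModel", function(x) x@r2xCum)

#' @describeIn PLSDAModel cumulative cross-validated Q2Y per factor.
#' @export
setMethod("q2yCum", "PLSDAModel", function(x) x@q2yCum)

setMethod("show", "PLSDAModel", function(object) {
  A <- object@nFactors
  cat(sprintf("PLSDAModel: %d classes (%s), %d factors selected\n",
              length(object@classes), paste(object@classes, collapse = ", "), A))
  cat(sprintf("  R2X_cum = %.4f  R2Y_cum = %.4f  Q2Y_cum = %.4f\n",
              object@r2xCum[A], object@r2yCum[A], object@q2yCum[A]))
  cat(sprintf("  cross-validation: %d random segments, seed %d\n",
              object@cvSpec$nSegments, object@cvSpec$seed))
})

setMethod("show", "ClassPredictionImage", function(object) {
  lv <- object@labels
  cat(sprintf("ClassPredictionImage: %d x %d pixels, classes: %s\n",
              nrow(lv), ncol(lv), paste(object@classes, collapse = ", ")))
  kept <- sum(!is.na(lv))
  cat(sprintf("  %d classified pixels, %.1f%% no_class\n", kept,
              100 * sum(lv == 0, na.rm = TRUE) / max(kept, 1)))
})

setMethod("show", "ScoreImage", function(object) {
  cat(sprintf("ScoreImage for component %d: %d x %d (bounds %.3g..%.3g)\n",
              object@component, nrow(object@values), ncol(object@values),
              object@bounds[1], object@bounds[2]))
})
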