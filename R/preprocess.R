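#' @include calibrate.R
NULL

#' Crop uninformative wavelengths
#'
#' Retains only the bands with wavelength strictly greater than `min_nm`.
#' The short-wave end of SWIR spectra (920-996 nm on the default grid)
#' typically carries no differentiating chemical information and is removed
#' before modeling.
#'
#' @param X pixel matrix (rows = spectra) or NULL to crop a grid alone.
#' @param wavelengths band wavelengths (nm), one per column of `X`.
#' @param min_nm bands with wavelength `<= min_nm` are dropped (default 996).
#' @return list with `spectra` (cropped matrix, or NULL), `wavelengths`
#'   (cropped grid) and `keep` (retained column indices).
#' @export
cropWavelengths <- function(X, wavelengths, min_nm = 996) {
  keep <- which(wavelengths > min_nm)
  if (length(keep) == 0L) stop("cropping at ", min_nm, " nm removes every band")
  list(spectra = if (is.null(X)) NULL else X[, keep, drop = FALSE],
       wavelengths = wavelengths[keep], keep = keep)
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum (row) to mean 0 and sample standard deviation
#' 1 (divisor n-1), removing per-pixel multiplicative scatter and additive
#' baseline offsets. Rows with standard deviation below `tol` cannot be
#' scaled; they are zero-filled and flagged.
#'
#' @param X pixel matrix, rows = spectra with at least 2 bands.
#' @param tol degenerate-row threshold on the standard deviation.
#' @return The transformed matrix with attribute `"flagged"`: integer
#'   indices of degenerate rows.
#' @export
snv <- function(X, tol = 1e-12) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  flagged <- which(sd < tol)
  sd[flagged] <- 1
  out <- Xc / sd
  out[flagged, ] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, and
#' returns `(x - a) / b`. Rows whose slope magnitude falls below `tol` are
#' passed through unchanged and flagged.
#'
#' @param X pixel matrix, rows = spectra.
#' @param reference `"mean"` (column mean of `X`) or a numeric spectrum of
#'   matching length.
#' @param tol degenerate-slope threshold.
#' @return The corrected matrix with attributes `"flagged"` (row indices)
#'   and `"reference"` (the reference spectrum used).
#' @export
msc <- function(X, reference = "mean", tol = 1e-12) {
  stopifnot(is.matrix(X))
  ref <- if (identical(reference, "mean")) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X)) stop("reference length must equal band count")
  rc <- ref - mean(ref)
  vref <- sum(rc^2)
  if (vref < tol) stop("MSC reference spectrum is constant")
  # per-row OLS of x on (1, ref): b = cov(x, ref)/var(ref), a = xbar - b*refbar
  b <- as.vector((X %*% rc) / vref)
  a <- rowMeans(X) - b * mean(ref)
  flagged <- which(abs(b) < tol)
  out <- (X - a) / ifelse(abs(b) < tol, 1, b)
  if (length(flagged)) out[flagged, ] <- X[flagged, , drop = FALSE]
  attr(out, "flagged") <- flagged
  attr(out, "reference") <- ref
  out
}

# Savitzky-Golay coefficient row for output position centered at offset
# `xs` (band-index offsets of the window points), derivative `deriv`,
# polynomial order `polyorder`: value = deriv! * row deriv of pinv(V).
.savgol_coef <- function(xs, polyorder, deriv) {
  V <- outer(xs, 0:polyorder, "^")
  Pinv <- solve(crossprod(V), t(V))
  factorial(deriv) * Pinv[deriv + 1, ]
}

#' Savitzky-Golay smoothed derivative
#'
#' Row-wise smoothed derivative with respect to band index, computed by
#' local polynomial least squares. Interior points use the full window;
#' edge points are fitted on the window truncated at the spectrum boundary
#' (the polynomial order is reduced there if the truncated window is too
#' short to support it).
#'
#' @param X pixel matrix, rows = spectra.
#' @param window odd window length, `<=` band count.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order, 1 or 2.
#' @return matrix of the same shape.
#' @export
savgolDerivative <- function(X, window = 11, polyorder = 2, deriv = 1) {
  stopifnot(is.matrix(X))
  p <- ncol(X)
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (!deriv %in% c(1, 2)) stop("deriv must be 1 or 2")
  if (window > p) stop("window (", window, ") exceeds band count (", p, ")")
  h <- (window - 1L) / 2L
  out <- matrix(0, nrow(X), p)
  interior <- .savgol_coef(-h:h, polyorder, deriv)
  for (j in seq_len(p)) {
    lo <- max(1L, j - h); hi <- min(p, j + h)
    if (lo == j - h && hi == j + h) {
      w <- interior
    } else {
      xs <- (lo:hi) - j
      ord <- min(polyorder, length(xs) - 1L)
      if (ord < deriv) { out[, j] <- 0; next }
      w <- .savgol_coef(xs, ord, deriv)
    }
    out[, j] <- X[, lo:hi, drop = FALSE] %*% w
  }
  out
}

#' Mean-center a pixel matrix
#'
#' Subtracts column (band) means and returns them so the identical centering
#' can be applied later to prediction pixels.
#'
#' @param X pixel matrix with at least 2 rows.
#' @param means optional stored means to apply instead of computing new ones.
#' @return centered matrix with attribute `"columnMeans"`.
#' @export
meanCenter <- function(X, means = NULL) {
  stopifnot(is.matrix(X))
  if (is.null(means)) {
    if (nrow(X) < 2) stop("mean centering needs at least 2 rows")
    means <- colMeans(X)
  }
  out <- sweep(X, 2, means, "-")
  attr(out, "columnMeans") <- means
  out
}

#' Fit a preprocessing plan on training pixels
#'
#' Applies the plan's steps in order to the training matrix and records all
#' data-dependent state (retained bands, MSC reference, column means) in a
#' [PreprocessState-class] so that [applyPreprocess()] replays exactly the
#' same transformation on new pixels.
#'
#' @param plan a [PreprocessPlan-class].
#' @param X training pixel matrix.
#' @param wavelengths band wavelengths matching `ncol(X)`.
#' @return list with `state` ([PreprocessState-class]), `spectra`
#'   (transformed matrix) and `wavelengths` (post-crop grid).
#' @export
fitPreprocess <- function(plan, X, wavelengths) {
  stopifnot(is(plan, "PreprocessPlan"))
  validObject(plan)
  keep <- seq_along(wavelengths)
  mscRef <- numeric(0)
  colMu <- numeric(0)
  wl <- wavelengths
  for (s in plan@steps) {
    switch(s$type,
      crop_wavelengths = {
        cr <- cropWavelengths(X, wl, s$min_nm)
        X <- cr$spectra; keep <- cr$keep; wl <- cr$wavelengths
      },
      snv = { X <- snv(X) },
      msc = {
        X <- msc(X, s$reference %||% "mean")
        mscRef <- attr(X, "reference")
      },
      savgol_derivative = {
        X <- savgolDerivative(X, s$window, s$polyorder, s$deriv)
      },
      mean_center = {
        X <- meanCenter(X)
        colMu <- attr(X, "columnMeans")
      })
  }
  state <- new("PreprocessState", plan = plan, wavelengthsIn = wavelengths,
               keepBands = as.integer(keep), mscReference = mscRef,
               columnMeans = colMu)
  list(state = state, spectra = X, wavelengths = wl)
}

#' Replay a fitted preprocessing pipeline on new pixels
#'
#' @param state a [PreprocessState-class] from [fitPreprocess()].
#' @param X new pixel matrix on the original (pre-crop) wavelength grid.
#' @return transformed matrix on the post-crop grid.
#' @export
applyPreprocess <- function(state, X) {
  stopifnot(is(state, "PreprocessState"), is.matrix(X))
  if (ncol(X) != length(state@wavelengthsIn))
    stop("new pixels have ", ncol(X), " bands; pipeline was fitted on ",
         length(state@wavelengthsIn))
  for (s in state@plan@steps) {
    switch(s$type,
      crop_wavelengths = { X <- X[, state@keepBands, drop = FALSE] },
      snv = { X <- snv(X) },
      msc = { X <- msc(X, state@mscReference) },
      savgol_derivative = { X <- savgolDerivative(X, s$window, s$polyorder, s$deriv) },
      mean_center = { X <- meanCenter(X, means = state@columnMeans) })
  }
  X
}

#' Post-crop wavelength grid of a fitted pipeline
#' @param state a [PreprocessState-class].
#' @return numeric vector.
#' @export
setMethod("wavelengths", "PreprocessState", function(x) x@wavelengthsIn[x@keepBands])

#' Class-separation score of a preprocessing plan
#'
#' Fits the plan and a small PCA to labeled pixels and returns the mean
#' silhouette width of the class labels in the first `nComp` score
#' dimensions. Used to compare candidate pretreatments by how well they
#' separate known classes; the plan is chosen by the analyst, not by an
#' optimizer.
#'
#' @param plan a [PreprocessPlan-class].
#' @param X labeled pixel matrix.
#' @param labels class label per row.
#' @param wavelengths band grid.
#' @param nComp number of PCA components for the score space (default 3).
#' @param maxPixels random subsample cap for the silhouette distance matrix
#'   (default 600); subsampling is stratified by label.
#' @param seed subsample seed.
#' @return mean silhouette width (numeric scalar in [-1, 1]).
#' @export
planSeparation <- function(plan, X, labels, wavelengths, nComp = 3,
                           maxPixels = 600, seed = 1) {
  fp <- fitPreprocess(plan, X, wavelengths)
  Z <- fp$spectra
  if (nrow(Z) > maxPixels) {
    per <- ceiling(maxPixels / length(unique(labels)))
    idx <- withSeed(seed, .stratified_subsample(labels, per))
    Z <- Z[idx, , drop = FALSE]; labels <- labels[idx]
  }
  pm <- fitPCA(Z, n_components = min(nComp, min(dim(Z)) - 1L))
  sc <- pm@scores
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(sc))
  mean(sil[, "sil_width"])
}
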