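#' @include pca.R
NULL

#' Flag dead pixels
#'
#' A pixel is dead when its spectrum is (numerically) constant — band-wise
#' variance below `var_tol` — or contains any non-finite value, or when the
#' cube's metadata carries a `saturated` logical matrix flagging it.
#'
#' @param cube a pseudo-absorbance [Hypercube-class].
#' @param var_tol variance threshold (default 1e-10).
#' @return logical (lines x samples) matrix, TRUE = dead.
#' @export
flagDeadPixels <- function(cube, var_tol = 1e-10) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@data)
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  nonfinite <- rowSums(!is.finite(X)) > 0
  Xf <- X; Xf[!is.finite(Xf)] <- 0
  v <- rowSums((Xf - rowMeans(Xf))^2) / (d[3] - 1)
  dead <- nonfinite | v < var_tol
  if (!is.null(cube@metadata$saturated))
    dead <- dead | as.vector(cube@metadata$saturated)
  matrix(dead, d[1], d[2])
}

#' Segment background pixels by PC1 + Otsu
#'
#' Automated replacement for interactive score-plot pixel selection. A
#' one-component mean-centered PCA (no scatter correction) is fitted to all
#' candidate pixels; an Otsu threshold on the PC1 score histogram splits the
#' pixels into two groups, and the group whose mean spectrum has the lower
#' overall absorbance is labeled background (`background = "low"`; set
#' `"high"` for stages that absorb more than the samples).
#'
#' @param cube a pseudo-absorbance [Hypercube-class] with >= 2 spatial pixels.
#' @param exclude optional logical matrix of pixels (e.g. dead ones) to
#'   exclude from the PCA and threshold; excluded pixels are reported as
#'   background = NA.
#' @param background which absorbance side is the stage: `"low"` (default)
#'   or `"high"`.
#' @return logical (lines x samples) matrix, TRUE = background (NA where
#'   excluded).
#' @export
segmentBackground <- function(cube, exclude = NULL, background = c("low", "high")) {
  stopifnot(is(cube, "Hypercube"))
  background <- match.arg(background)
  d <- dim(cube@data)
  if (d[1] * d[2] < 2) stop("need at least 2 spatial pixels")
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  use <- if (is.null(exclude)) rep(TRUE, nrow(X)) else !as.vector(exclude)
  Xu <- X[use, , drop = FALSE]
  fit <- fitPCA(Xu, n_components = 1L)   # errors on zero-variance input
  t1 <- fit@scores[, 1]
  thr <- EBImage::otsu(matrix(t1, ncol = 1), range = range(t1), levels = 256)
  hi <- t1 > thr
  if (all(hi) || !any(hi)) hi <- t1 > 0   # degenerate histogram: sign split
  if (all(hi) || !any(hi))
    stop("background segmentation degenerate: PC1 scores do not split")
  mean_hi <- mean(Xu[hi, , drop = FALSE])
  mean_lo <- mean(Xu[!hi, , drop = FALSE])
  bg_is_hi <- if (background == "low") mean_hi < mean_lo else mean_hi > mean_lo
  bg_u <- if (bg_is_hi) hi else !hi
  bg <- rep(NA, nrow(X))
  bg[use] <- bg_u
  matrix(bg, d[1], d[2])
}

#' Erode the kept region of a mask
#'
#' Removes boundary pixels of the kept set by binary erosion with a
#' 4-connected (diamond) structuring element, applied `iterations` times.
#' Newly removed pixels get provenance `"edge"`. This strips mixed
#' sample/stage boundary pixels ("edge effects").
#'
#' @param mask a [PixelMask-class].
#' @param iterations number of erosion passes (default 1; 0 = identity).
#' @return the eroded [PixelMask-class].
#' @export
erodeEdges <- function(mask, iterations = 1L) {
  stopifnot(is(mask, "PixelMask"), iterations >= 0)
  keep <- keepMatrix(mask)
  prov <- maskProvenance(mask)
  if (iterations > 0) {
    kern <- EBImage::makeBrush(3, shape = "diamond")
    km <- keep * 1
    for (i in seq_len(iterations)) km <- EBImage::erode(km, kern)
    newkeep <- km > 0.5
    prov[keep & !newkeep] <- "edge"
    keep <- newkeep
  }
  PixelMask(keep, prov)
}

#' Build the full pixel mask for a scene
#'
#' Chains the three automated masking steps: dead-pixel flagging,
#' PC1 + Otsu background segmentation (with dead pixels excluded before
#' thresholding), and edge erosion. Provenance precedence is
#' dead > background > edge.
#'
#' @param cube a pseudo-absorbance [Hypercube-class].
#' @param erode_iterations erosion passes (default 1).
#' @param background see [segmentBackground()].
#' @return a [PixelMask-class].
#' @export
buildPixelMask <- function(cube, erode_iterations = 1L,
                           background = c("low", "high")) {
  background <- match.arg(background)
  dead <- flagDeadPixels(cube)
  bg <- segmentBackground(cube, exclude = dead, background = background)
  prov <- matrix("kept", nrow(dead), ncol(dead))
  prov[!is.na(bg) & bg] <- "background"
  prov[dead] <- "dead"
  mask <- PixelMask(prov == "kept", prov)
  erodeEdges(mask, erode_iterations)
}
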