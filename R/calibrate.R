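#' @include envi.R
NULL

# cube array (lines x samples x bands) <-> pixel matrix (lines*samples x bands)
# pixel row i corresponds to (line, sample) with line running fastest.
.cube_to_matrix <- function(cube) {
  d <- dim(cube@data)
  matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
}

.pixel_index <- function(lines, line, sample) (sample - 1L) * lines + line

.reference_band_means <- function(ref, wavelengths) {
  if (is(ref, "Hypercube")) {
    if (length(ref@wavelengths) != length(wavelengths) ||
        max(abs(ref@wavelengths - wavelengths)) > 1e-6)
      stop("reference cube is not on the scene's wavelength grid")
    apply(ref@data, 3, mean)
  } else {
    if (length(ref) != length(wavelengths))
      stop("reference vector length does not match band count")
    as.numeric(ref)
  }
}

#' Calibrate raw counts to reflectance
#'
#' Converts a raw-counts cube to reflectance using the per-band spatial
#' means of the dark and white reference measurements:
#' \deqn{R = (raw - \bar{dark}) / (\bar{white} - \bar{dark})}
#' Values are clipped to `[epsR, rMax]` so that the subsequent log
#' transform is finite even for dead or specular pixels.
#'
#' @param raw a raw-counts [Hypercube-class].
#' @param refs a [ReferencePair-class] on the same wavelength grid.
#' @param epsR reflectance floor (default 1e-6).
#' @param rMax reflectance ceiling (default 1.5).
#' @return A reflectance [Hypercube-class].
#' @export
calibrateReflectance <- function(raw, refs, epsR = 1e-6, rMax = 1.5) {
  stopifnot(is(raw, "Hypercube"), is(refs, "ReferencePair"))
  if (raw@signalKind != "raw_counts")
    stop("calibrateReflectance expects a raw_counts cube, got ", raw@signalKind)
  wl <- raw@wavelengths
  dk <- .reference_band_means(refs@dark, wl)
  wt <- .reference_band_means(refs@white, wl)
  denom <- wt - dk
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf("white reference <= dark reference at band %d (%.1f nm)",
                 bad[1], wl[bad[1]]))
  d <- dim(raw@data)
  X <- matrix(raw@data, nrow = d[1] * d[2], ncol = d[3])
  R <- sweep(sweep(X, 2, dk, "-"), 2, denom, "/")
  R <- pmin(pmax(R, epsR), rMax)
  Hypercube(array(R, d), wl, signalKind = "reflectance",
            metadata = raw@metadata, rMax = rMax)
}

#' Convert reflectance to pseudo-absorbance
#'
#' Elementwise `A = log10(1/R)`. Because [calibrateReflectance()] clips
#' reflectance away from zero, the result is finite everywhere.
#'
#' @param refl a reflectance [Hypercube-class].
#' @return A pseudo-absorbance [Hypercube-class].
#' @export
toPseudoAbsorbance <- function(refl) {
  stopifnot(is(refl, "Hypercube"))
  if (refl@signalKind != "reflectance")
    stop("toPseudoAbsorbance expects a reflectance cube, got ", refl@signalKind)
  Hypercube(-log10(refl@data), refl@wavelengths,
            signalKind = "pseudo_absorbance", metadata = refl@metadata)
}

#' Logical membership matrix of one region
#'
#' @param shape `"rect"` or `"disk"`.
#' @param params rect: `c(y0, x0, y1, x1)` (0-based, half-open);
#'   disk: `c(cy, cx, r)` (0-based center, inclusive radius).
#' @param dims spatial dimensions `c(lines, samples)`.
#' @return logical lines x samples matrix.
#' @keywords internal
.region_membership <- function(shape, params, dims) {
  nl <- dims[1]; ns <- dims[2]
  if (shape == "rect") {
    y <- seq_len(nl) - 1L; x <- seq_len(ns) - 1L
    outer(y >= params[1] & y < params[3], x >= params[2] & x < params[4], "&")
  } else {
    y <- (seq_len(nl) - 1L) - params[1]
    x <- (seq_len(ns) - 1L) - params[2]
    outer(y^2, x^2, "+") <= params[3]^2
  }
}

#' Extract labeled pixel spectra from regions
#'
#' Collects the spectra of all kept pixels inside each region of a layout
#' into one matrix, keeping the region label, claimed class and the spatial
#' coordinates of every row so results can be mapped back onto the image.
#'
#' @param cube a [Hypercube-class].
#' @param layout a [RegionLayout-class].
#' @param mask optional [PixelMask-class]; if NULL all pixels are kept.
#' @return A list with elements `spectra` (n x bands matrix), `label`
#'   (character, per row), `class_hint` (character, per row), `coords`
#'   (data.frame `y`, `x`, 0-based), and `wavelengths`. Regions with zero
#'   kept pixels produce a warning and contribute no rows.
#' @export
extractRegionSpectra <- function(cube, layout, mask = NULL) {
  stopifnot(is(cube, "Hypercube"), is(layout, "RegionLayout"))
  d <- dim(cube@data)
  keep <- if (is.null(mask)) matrix(TRUE, d[1], d[2]) else keepMatrix(mask)
  if (!identical(dim(keep), d[1:2]))
    stop("mask dimensions do not match cube spatial dimensions")
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  regs <- layout@regions
  out_idx <- integer(0); out_lab <- character(0); out_hint <- character(0)
  for (i in seq_len(nrow(regs))) {
    memb <- .region_membership(regs$shape[i],
                               as.numeric(regs[i, c("p1", "p2", "p3", "p4")]),
                               d[1:2])
    idx <- which(memb & keep)
    if (length(idx) == 0L) {
      warning("region '", regs$label[i], "' contains no kept pixels")
      next
    }
    out_idx <- c(out_idx, idx)
    out_lab <- c(out_lab, rep(regs$label[i], length(idx)))
    out_hint <- c(out_hint, rep(regs$class_hint[i], length(idx)))
  }
  coords <- data.frame(y = ((out_idx - 1L) %% d[1]),
                       x = ((out_idx - 1L) %/% d[1]))
  list(spectra = X[out_idx, , drop = FALSE], label = out_lab,
       class_hint = out_hint, coords = coords, wavelengths = cube@wavelengths)
}

#' Read / write a region layout CSV
#'
#' The CSV has columns `label`, `class_hint`, `shape` and `params`, with
#' `params` a semicolon-separated numeric list (rect: `y0;x0;y1;x1`,
#' disk: `cy;cx;r`).
#'
#' @param path CSV file path.
#' @return [readRegionLayout()]: a [RegionLayout-class].
#' @export
readRegionLayout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(params = "character"))
  params <- lapply(strsplit(df$params, ";", fixed = TRUE), as.numeric)
  RegionLayout(df$label, df$class_hint, df$shape, params)
}

#' @param layout a [RegionLayout-class].
#' @rdname readRegionLayout
#' @return [writeRegionLayout()]: invisibly, the path.
#' @export
writeRegionLayout <- function(layout, path) {
  r <- layout@regions
  params <- apply(r[, c("p1", "p2", "p3", "p4")], 1, function(p)
    paste(formatC(p[!is.na(p)], format = "g", digits = 10), collapse = ";"))
  utils::write.csv(data.frame(label = r$label, class_hint = r$class_hint,
                              shape = r$shape, params = params),
                   path, row.names = FALSE)
  invisible(path)
}
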