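#' @include preprocess.R utils.R
NULL

#' Fit a NIPALS principal component analysis
#'
#' Extracts components one at a time by the NIPALS algorithm with
#' deflation, the standard chemometric formulation: iterate
#' `p = X't / t't`, normalize `p`, `t = X p` until the score vector is
#' stable, then deflate `X <- X - t p'`. Per-component explained variance
#' is `R2X_a = (t_a' t_a) / SS` with SS the total centered sum of squares.
#'
#' Each loading column's sign is flipped so its largest-magnitude element
#' is positive, making runs reproducible.
#'
#' @param X pixel matrix (rows = observations). Centered internally; the
#'   mean is stored in the model.
#' @param n_components number of components A, `<= min(dim(X))`.
#' @param tol convergence tolerance on the relative score-vector change
#'   (default 1e-9).
#' @param max_iter iteration cap per component (default 500); hitting it
#'   raises a warning and accepts the current vector.
#' @param center set FALSE if `X` is already column-centered.
#' @param wavelengths optional band grid stored for plotting.
#' @return A [PCAModel-class]. When the numerical rank of the matrix is
#'   exhausted before `n_components`, the model carries only the
#'   extractable components.
#' @export
fitPCA <- function(X, n_components, tol = 1e-9, max_iter = 500,
                   center = TRUE, wavelengths = numeric(0)) {
  stopifnot(is.matrix(X))
  if (n_components > min(dim(X)))
    stop("n_components must not exceed min(dim(X))")
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu, "-")
  totSS <- sum(Xc^2)
  if (totSS < 1e-300) stop("matrix has zero variance; PCA undefined")
  P <- matrix(0, ncol(X), n_components)
  Tm <- matrix(0, nrow(X), n_components)
  r2 <- numeric(n_components)
  n_done <- 0L
  for (a in seq_len(n_components)) {
    # numerical rank exhausted: stop and return the components found
    if (sum(Xc^2) < totSS * 1e-24) break
    t <- Xc[, which.max(colSums(Xc^2))]
    for (it in seq_len(max_iter)) {
      p <- as.vector(crossprod(Xc, t)) / sum(t^2)
      p <- p / sqrt(sum(p^2))
      t_new <- as.vector(Xc %*% p)
      dd <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- t_new
      if (dd < tol) break
      if (it == max_iter)
        warning("NIPALS did not converge for component ", a,
                "; accepting current vector")
    }
    j <- which.max(abs(p))
    if (p[j] < 0) { p <- -p; t <- -t }
    P[, a] <- p
    Tm[, a] <- t
    r2[a] <- sum(t^2) / totSS
    Xc <- Xc - tcrossprod(t, p)
    n_done <- a
  }
  keep <- seq_len(n_done)
  new("PCAModel", center = mu, loadings = P[, keep, drop = FALSE],
      scores = Tm[, keep, drop = FALSE], r2x = r2[keep],
      r2xCum = cumsum(r2[keep]), totalSS = totSS,
      wavelengths = as.numeric(wavelengths))
}

#' Project new pixels onto a PCA model
#'
#' @param model a [PCAModel-class].
#' @param X new pixel matrix on the model's band grid.
#' @return score matrix `(X - mean) P`.
#' @export
projectPixels <- function(model, X) {
  stopifnot(is(model, "PCAModel"), is.matrix(X))
  if (ncol(X) != length(model@center))
    stop("band count mismatch: model has ", length(model@center),
         ", new data has ", ncol(X))
  sweep(X, 2, model@center, "-") %*% model@loadings
}

#' Build a score image for one component
#'
#' Spatial amplitude map of one component's scores: kept pixels carry their
#' score, removed pixels are NA. Color-scale bounds default to symmetric
#' `+/- max(|score|)`.
#'
#' @param scores score vector or matrix whose rows correspond to the kept
#'   pixels of `mask` in row-of-`which(keep)` order (as produced by
#'   [extractRegionSpectra()] / [projectPixels()] over `which(keepMatrix(mask))`).
#' @param mask a [PixelMask-class].
#' @param component which component to map (default 1).
#' @return A [ScoreImage-class].
#' @export
makeScoreImage <- function(scores, mask, component = 1L) {
  if (is.matrix(scores)) {
    if (component > ncol(scores)) stop("component exceeds score columns")
    scores <- scores[, component]
  }
  keep <- keepMatrix(mask)
  if (length(scores) != sum(keep))
    stop("score length (", length(scores), ") != kept pixel count (", sum(keep), ")")
  vals <- matrix(NA_real_, nrow(keep), ncol(keep))
  vals[which(keep)] <- scores
  b <- max(abs(scores))
  new("ScoreImage", values = vals, component = as.integer(component),
      bounds = c(-b, b))
}

#' Loadings line-plot data and discriminating window
#'
#' Returns one component's loading vector aligned to its wavelengths,
#' together with the contiguous wavelength window of a given width that
#' maximizes the mean absolute loading — the region carrying the most
#' discriminating spectral information.
#'
#' @param model a [PCAModel-class] fitted with `wavelengths`.
#' @param component component index (default 1).
#' @param window_nm window width in nm (default 300).
#' @return list with `wavelengths`, `loading`, `window` (`c(lo, hi)` nm),
#'   `window_mean_abs` and `informative` (FALSE when the loadings are flat
#'   and every window ties).
#' @export
loadingsLinePlotData <- function(model, component = 1L, window_nm = 300) {
  stopifnot(is(model, "PCAModel"))
  if (component > ncol(model@loadings)) stop("component exceeds model size")
  wl <- model@wavelengths
  if (length(wl) != nrow(model@loadings))
    stop("model carries no wavelength grid")
  p <- model@loadings[, component]
  ap <- abs(p)
  best <- -Inf; best_i <- 1L; best_j <- 1L
  means <- numeric(length(wl))
  for (i in seq_along(wl)) {
    j <- max(which(wl <= wl[i] + window_nm))
    means[i] <- mean(ap[i:j])
    if (means[i] > best + 1e-15) { best <- means[i]; best_i <- i; best_j <- j }
  }
  informative <- diff(range(means)) > 1e-12 * max(abs(means), 1e-300)
  list(wavelengths = wl, loading = p,
       window = c(wl[best_i], wl[best_j]),
       window_mean_abs = best, informative = informative)
}

#' Select the number of PCA components by cross-validation
#'
#' Splits rows into random segments; for each held-out row, every matrix
#' entry is predicted from the row's *other* bands through the loadings
#' fitted on the remaining segments (leave-one-variable-out scores, so the
#' held-out entry never participates in its own prediction — plain
#' projection reconstruction would let even pure noise look predictive).
#' Returns the smallest A after which adding a component improves the
#' cross-validated explained variance by less than `delta`.
#'
#' @param X pixel matrix.
#' @param max_A largest component count to consider.
#' @param n_segments number of CV segments (default 7).
#' @param delta minimum cross-validated gain to accept a component
#'   (default 0.01).
#' @param seed RNG seed for segment membership.
#' @return integer A (at least 1, at most `max_A`).
#' @export
selectNComponents <- function(X, max_A, n_segments = 7, delta = 0.01, seed = 1) {
  stopifnot(is.matrix(X), max_A >= 1)
  max_A <- min(max_A, min(dim(X)) - 1L)
  n <- nrow(X)
  if (n < n_segments) stop("fewer rows than CV segments")
  seg <- withSeed(seed, sample(rep_len(seq_len(n_segments), n)))
  press <- numeric(max_A)
  ss <- 0
  p <- ncol(X)
  for (k in seq_len(n_segments)) {
    tr <- X[seg != k, , drop = FALSE]
    va <- X[seg == k, , drop = FALSE]
    mu <- colMeans(tr)
    # the CV criterion only needs the leading principal subspace of the
    # training rows; computed by exact SVD (NIPALS would grind on the
    # near-degenerate noise components whose rotation is irrelevant here)
    sv <- svd(sweep(tr, 2, mu, "-"), nu = 0, nv = max_A)
    P <- sv$v
    Vc <- sweep(va, 2, mu, "-")
    ss <- ss + sum(Vc^2)
    Tfull <- Vc %*% P
    # Sherman-Morrison collapses the per-band leave-out prediction to the
    # plain projection residual scaled by 1/(1 - h_j), h_j the leverage of
    # band j in the loading rows (the PCA analogue of the regression LOO
    # identity)
    res <- Vc
    h <- numeric(p)
    for (a in seq_len(max_A)) {
      if (a <= ncol(P)) {
        res <- res - tcrossprod(Tfull[, a], P[, a])
        h <- h + P[, a]^2
      }
      g <- pmax(1 - h, 1e-8)
      press[a] <- press[a] + sum(colSums(res^2) / g^2)
    }
  }
  q2 <- 1 - press / ss
  gains <- diff(c(0, q2))
  A <- 1L
  for (a in seq_len(max_A)) {
    if (gains[a] >= delta) A <- a else break
  }
  A
}
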