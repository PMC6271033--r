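#' @include pca.R
NULL

#' Encode class labels as a dummy Y matrix
#'
#' One-hot encoding of per-pixel class labels against an ordered class
#' codebook, the categorical Y block of PLS-DA.
#'
#' @param labels character vector of training-pixel labels.
#' @param classes ordered class labels (the codebook), >= 2 unique values.
#' @return n x length(classes) matrix of 0/1 with unit row sums.
#' @examples
#' encodeClasses(c("B", "A"), classes = c("A", "B", "C"))
#' @export
encodeClasses <- function(labels, classes) {
  if (length(classes) < 2 || anyDuplicated(classes))
    stop("codebook needs >= 2 unique classes")
  idx <- match(labels, classes)
  if (anyNA(idx))
    stop("unknown label(s): ", paste(unique(labels[is.na(idx)]), collapse = ", "))
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

# NIPALS PLS2 on centered X, Y; returns W, P, Q, T and per-factor explained SS
.nipals_pls2 <- function(Xc, Yc, A, tol = 1e-9, max_iter = 500) {
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, m, A); Tm <- matrix(0, n, A)
  ssx_f <- numeric(A); ssy_f <- numeric(A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    if (sum(u^2) < 1e-300) { A <- a - 1L; break }
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- as.vector(crossprod(Xc, u)) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- as.vector(Xc %*% w)
      q <- as.vector(crossprod(Yc, tt)) / sum(tt^2)
      u <- as.vector(Yc %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) / sqrt(sum(tt^2)) < tol) break
      t_old <- tt
      if (it == max_iter)
        warning("PLS factor ", a, " did not converge; accepting current vector")
    }
    pp <- as.vector(crossprod(Xc, tt)) / sum(tt^2)
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; tt <- -tt; pp <- -pp; q <- -q }
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    ssx_f[a] <- sum(tt^2) * sum(pp^2)
    ssy_f[a] <- sum(tt^2) * sum(q^2)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, q)
  }
  list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
       Q = Q[, seq_len(A), drop = FALSE], T = Tm[, seq_len(A), drop = FALSE],
       ssx_factor = ssx_f[seq_len(A)], ssy_factor = ssy_f[seq_len(A)], A = A)
}

# regression coefficients B = W (P'W)^-1 Q' using the first `a` factors
.pls_coefficients <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS-DA model with cross-validated factor selection
#'
#' NIPALS PLS2 regression of preprocessed spectra against a one-hot class
#' matrix. The number of factors is chosen by Q2Y_cum from random-segment
#' cross-validation: pixel rows are split into `n_segments` random
#' segments (stratified by class so no fold loses a class), each segment
#' is left out once, and
#' \deqn{Q^2Y_{cum}(a) = 1 - PRESS(a) / SS(Y_{centered})}
#' with PRESS pooled over Y columns and segments. Factors are accepted
#' while the marginal gain `Q2Y_cum(a) - Q2Y_cum(a-1)` is at least
#' `delta`; the selected A is the last accepted factor.
#'
#' @param X preprocessed pixel matrix.
#' @param Y dummy class matrix from [encodeClasses()] (same row count).
#' @param max_A largest factor count to evaluate.
#' @param n_segments number of cross-validation segments (default 7).
#' @param delta minimum significant Q2Y_cum gain (default 0.01).
#' @param seed RNG seed for segment membership.
#' @param tol,max_iter NIPALS convergence controls.
#' @return A [PLSDAModel-class].
#' @export
fitPLSDA <- function(X, Y, max_A = 10, n_segments = 7, delta = 0.01,
                     seed = 1, tol = 1e-9, max_iter = 500) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  classes <- colnames(Y)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < n_segments) stop("fewer rows (", n, ") than CV segments (", n_segments, ")")
  max_A <- min(max_A, min(dim(X)))
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm, "-"); Yc <- sweep(Y, 2, ym, "-")
  ssy <- sum(Yc^2)

  # CV segments: random membership, stratified by class, each left out once
  cls <- max.col(Y)
  seg <- integer(n)
  withSeed(seed, for (k in unique(cls)) {
    ii <- which(cls == k)
    seg[ii] <- sample(rep_len(sample(n_segments), length(ii)))
  })
  press <- numeric(max_A)
  for (k in seq_len(n_segments)) {
    tr <- seg != k
    xmk <- colMeans(X[tr, , drop = FALSE]); ymk <- colMeans(Y[tr, , drop = FALSE])
    fit_k <- .nipals_pls2(sweep(X[tr, , drop = FALSE], 2, xmk, "-"),
                          sweep(Y[tr, , drop = FALSE], 2, ymk, "-"),
                          max_A, tol, max_iter)
    Xv <- sweep(X[!tr, , drop = FALSE], 2, xmk, "-")
    Yv <- Y[!tr, , drop = FALSE]
    press_last <- sum(sweep(Yv, 2, ymk, "-")^2)  # 0-factor baseline
    for (a in seq_len(max_A)) {
      if (a > fit_k$A) { press[a] <- press[a] + press_last; next }
      Bk <- .pls_coefficients(fit_k, a)
      Ehat <- sweep(Xv %*% Bk, 2, ymk, "+") - Yv
      press_last <- sum(Ehat^2)
      press[a] <- press[a] + press_last
    }
  }
  q2 <- 1 - press / ssy

  gains <- diff(c(0, q2))
  A <- 1L
  for (a in seq_len(max_A)) if (gains[a] >= delta) A <- a else break

  fit <- .nipals_pls2(Xc, Yc, max_A, tol, max_iter)
  nEval <- fit$A
  r2x <- cumsum(fit$ssx_factor) / sum(Xc^2)
  r2y <- cumsum(fit$ssy_factor) / ssy
  A <- min(A, nEval)
  B <- .pls_coefficients(fit, A)
  dimnames(B) <- list(NULL, classes)
  new("PLSDAModel", classes = classes, xMean = xm, yMean = ym,
      weights = fit$W, xLoadings = fit$P, yLoadings = fit$Q,
      scores = fit$T, coefficients = B, nFactors = as.integer(A),
      r2xCum = r2x, r2yCum = r2y, q2yCum = q2[seq_len(nEval)],
      cvSpec = list(nSegments = as.integer(n_segments), seed = as.integer(seed),
                    delta = delta, method = "random segments"))
}

#' Predict continuous dummy-Y values
#'
#' @param model a [PLSDAModel-class].
#' @param X new preprocessed pixel matrix on the model's band grid.
#' @return n x classes matrix `Yhat = (X - xMean) B + yMean`.
#' @export
predictContinuous <- function(model, X) {
  stopifnot(is(model, "PLSDAModel"), is.matrix(X))
  if (ncol(X) != length(model@xMean))
    stop("band count mismatch: model has ", length(model@xMean),
         ", new data has ", ncol(X))
  sweep(sweep(X, 2, model@xMean, "-") %*% model@coefficients, 2,
        model@yMean, "+")
}

#' Classify continuous predictions with Y cut-offs
#'
#' A class is a candidate for a pixel when its predicted dummy-Y value lies
#' inside `[min_cut, max_cut]`. One candidate assigns that class; several
#' candidates are resolved by the largest Yhat; none assigns `no_class`.
#'
#' @param Yhat n x classes matrix of continuous predictions.
#' @param min_cut,max_cut the class membership window (defaults 0.5, 1.5).
#' @return integer vector: 0 = no_class, k = k-th class.
#' @export
classifyYhat <- function(Yhat, min_cut = 0.5, max_cut = 1.5) {
  stopifnot(is.matrix(Yhat), min_cut < max_cut)
  inwin <- Yhat >= min_cut & Yhat <= max_cut
  Ymask <- Yhat
  Ymask[!inwin] <- -Inf
  lab <- max.col(Ymask, ties.method = "first")
  lab[rowSums(inwin) == 0] <- 0L
  as.integer(lab)
}

#' Build a per-pixel class prediction image
#'
#' @param model a [PLSDAModel-class].
#' @param Yhat continuous predictions for the kept pixels of `mask`, rows in
#'   `which(keepMatrix(mask))` order.
#' @param mask a [PixelMask-class].
#' @param min_cut,max_cut Y cut-offs (defaults 0.5, 1.5).
#' @return A [ClassPredictionImage-class].
#' @export
classifyPixels <- function(model, Yhat, mask, min_cut = 0.5, max_cut = 1.5) {
  stopifnot(is(model, "PLSDAModel"))
  keep <- keepMatrix(mask)
  if (nrow(Yhat) != sum(keep))
    stop("Yhat rows (", nrow(Yhat), ") != kept pixels (", sum(keep), ")")
  lab <- classifyYhat(Yhat, min_cut, max_cut)
  labels <- matrix(NA_integer_, nrow(keep), ncol(keep))
  labels[which(keep)] <- lab
  ya <- array(NA_real_, c(dim(keep), ncol(Yhat)))
  for (c in seq_len(ncol(Yhat))) {
    plane <- matrix(NA_real_, nrow(keep), ncol(keep))
    plane[which(keep)] <- Yhat[, c]
    ya[, , c] <- plane
  }
  new("ClassPredictionImage", classes = model@classes, labels = labels, yhat = ya)
}

.parse_hint <- function(hint) {
  if (is.na(hint) || !nzchar(hint)) return(character(0))
  trimws(strsplit(hint, "[+;|]")[[1]])
}

#' Quantify per-region species composition
#'
#' For every region of the layout, the percentage of kept pixels predicted
#' as each class and as `no_class` (denominator = kept pixels in the
#' region), the dominant prediction, and a verdict against the region's
#' claimed composition: `"match"` when the dominant class appears in the
#' claim, `"mismatch"` when it does not, `"no_authentic_material"` when
#' `no_class` dominates, `"unevaluable"` for regions with no kept pixels,
#' NA when no claim was given.
#'
#' @param pred a [ClassPredictionImage-class].
#' @param layout a [RegionLayout-class].
#' @return data.frame (one row per region): `region`, `class_hint`, one
#'   percentage column per class, `no_class`, `n_pixels`, `dominant`,
#'   `verdict`. Percentages sum to 100 per evaluable region.
#' @export
quantifyComposition <- function(pred, layout) {
  stopifnot(is(pred, "ClassPredictionImage"), is(layout, "RegionLayout"))
  classes <- pred@classes
  regs <- layout@regions
  d <- dim(pred@labels)
  out <- data.frame(region = regs$label, class_hint = regs$class_hint,
                    stringsAsFactors = FALSE)
  pct <- matrix(NA_real_, nrow(regs), length(classes) + 1,
                dimnames = list(NULL, c(classes, "no_class")))
  n_pixels <- integer(nrow(regs))
  dominant <- character(nrow(regs)); verdict <- character(nrow(regs))
  for (i in seq_len(nrow(regs))) {
    memb <- .region_membership(regs$shape[i],
                               as.numeric(regs[i, c("p1", "p2", "p3", "p4")]), d)
    lab <- pred@labels[memb]
    lab <- lab[!is.na(lab)]
    n_pixels[i] <- length(lab)
    if (length(lab) == 0L) {
      dominant[i] <- NA_character_; verdict[i] <- "unevaluable"
      next
    }
    counts <- tabulate(lab + 1L, nbins = length(classes) + 1L)  # bin 1 = no_class
    pcts <- 100 * c(counts[-1], counts[1]) / length(lab)
    pct[i, ] <- pcts
    dom <- which.max(pcts)
    dominant[i] <- colnames(pct)[dom]
    hints <- .parse_hint(regs$class_hint[i])
    verdict[i] <- if (length(hints) == 0) NA_character_
      else if (dominant[i] == "no_class") "no_authentic_material"
      else if (dominant[i] %in% hints) "match" else "mismatch"
  }
  cbind(out, as.data.frame(pct), n_pixels = n_pixels,
        dominant = dominant, verdict = verdict)
}

#' Validate a model on held-out labeled regions
#'
#' Predicts held-out pixels, compares against their true classes, and
#' summarizes accuracy per region and per pixel.
#'
#' @param model a [PLSDAModel-class].
#' @param X preprocessed held-out pixel matrix.
#' @param region character vector: region id per row.
#' @param true_class character vector: true class per row (values from the
#'   model's codebook).
#' @param min_cut,max_cut Y cut-offs.
#' @return list: `region_summary` (data.frame with region, true class,
#'   dominant predicted class, correctness, pixel accuracy), `confusion`
#'   (true class x predicted class counts, including `no_class`),
#'   `pixel_accuracy`, `misclassified_fraction`,
#'   `region_accuracy` (fraction of regions whose dominant class is right).
#' @export
externalValidation <- function(model, X, region, true_class,
                               min_cut = 0.5, max_cut = 1.5) {
  stopifnot(length(region) == nrow(X), length(true_class) == nrow(X))
  if (nrow(X) == 0L) stop("empty test set")
  classes <- model@classes
  lab <- classifyYhat(predictContinuous(model, X), min_cut, max_cut)
  predf <- factor(c("no_class", classes)[lab + 1L], levels = c(classes, "no_class"))
  truef <- factor(true_class, levels = classes)
  confusion <- table(true = truef, predicted = predf)
  correct_pix <- !is.na(truef) & as.character(predf) == as.character(truef)
  regs <- unique(region)
  dominant <- vapply(regs, function(r) {
    tab <- table(predf[region == r])
    names(tab)[which.max(tab)]
  }, character(1))
  true_by_region <- vapply(regs, function(r) unique(true_class[region == r])[1],
                           character(1))
  acc_by_region <- vapply(regs, function(r) mean(correct_pix[region == r]),
                          numeric(1))
  summary <- data.frame(region = regs, true_class = true_by_region,
                        dominant = dominant,
                        correct = dominant == true_by_region,
                        pixel_accuracy = acc_by_region,
                        stringsAsFactors = FALSE)
  list(region_summary = summary, confusion = confusion,
       pixel_accuracy = mean(correct_pix),
       misclassified_fraction = mean(!correct_pix),
       region_accuracy = mean(summary$correct))
}
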