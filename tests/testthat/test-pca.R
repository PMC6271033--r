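test_that("NIPALS recovers exact low-rank structure", {
  set.seed(40)
  u <- rnorm(30); v <- rnorm(12)
  X <- tcrossprod(u, v) + 5
  m <- fitPCA(X, n_components = 1)
  expect_equal(r2xCum(m)[1], 1, tolerance = 1e-10)

  # full decomposition explains everything
  Xf <- rand_matrix(15, 6, seed = 41)
  mf <- fitPCA(Xf, n_components = 6)
  expect_equal(r2xCum(mf)[6], 1, tolerance = 1e-8)
  expect_error(fitPCA(matrix(2, 5, 4), 1), "zero variance")
})

test_that("NIPALS matches the truncated SVD oracle on random matrices", {
  for (s in 1:10) {
    X <- rand_matrix(40, 25, seed = 100 + s)
    A <- 4
    m <- fitPCA(X, n_components = A, tol = 1e-13, max_iter = 20000)
    Xc <- scale(X, scale = FALSE)
    sv <- svd(Xc, nu = A, nv = A)
    for (a in seq_len(A)) {
      p_or <- sv$v[, a]; t_or <- sv$u[, a] * sv$d[a]
      if (sign(p_or[which.max(abs(p_or))]) < 0) { p_or <- -p_or; t_or <- -t_or }
      expect_lt(max(abs(modelLoadings(m)[, a] - p_or)), 1e-6)
      expect_lt(max(abs(modelScores(m)[, a] - t_or)), 1e-6)
    }
    # residual SS identity: ||X - mean - T P'||^2 = (1 - r2x_cum[A]) * totSS
    recon <- tcrossprod(modelScores(m), modelLoadings(m))
    res <- sum((Xc - recon)^2)
    expect_equal(res, (1 - r2xCum(m)[A]) * sum(Xc^2),
                 tolerance = 1e-8)
  }
})

test_that("projection reproduces training scores and is a plain matrix product", {
  X <- rand_matrix(30, 10, seed = 50)
  m <- fitPCA(X, 3, tol = 1e-13, max_iter = 20000)
  expect_lt(max(abs(projectPixels(m, X) - modelScores(m))), 1e-8)
  expect_equal(as.vector(projectPixels(m, matrix(m@center, 1))), rep(0, 3))
  Xn <- rand_matrix(5, 10, seed = 51)
  oracle <- sweep(Xn, 2, m@center) %*% modelLoadings(m)
  expect_equal(projectPixels(m, Xn), oracle)
  expect_error(projectPixels(m, Xn[, 1:4]), "band count mismatch")
})

test_that("score images place scores spatially and NA the removed pixels", {
  keep <- matrix(TRUE, 2, 2)
  mask <- PixelMask(keep)
  scores <- c(1, 2, 3, 4)
  img <- makeScoreImage(scores, mask)
  expect_equal(img@values, matrix(scores, 2, 2))
  expect_equal(img@bounds, c(-4, 4))

  keep2 <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  img2 <- makeScoreImage(c(10, -2, 7), PixelMask(keep2))
  expect_true(is.na(img2@values[2, 1]))

  # per-region mean score equals a brute-force mean over region pixels
  set.seed(52)
  keep3 <- matrix(runif(64) > 0.2, 8, 8)
  sc <- rnorm(sum(keep3))
  img3 <- makeScoreImage(sc, PixelMask(keep3))
  memb <- hsichem:::.region_membership("rect", c(1, 2, 6, 7), c(8, 8))
  expect_equal(mean(img3@values[memb & keep3]),
               mean(img3@values[memb], na.rm = TRUE))
})

test_that("the discriminating window maximizes mean absolute loading", {
  wl <- seq(1000, 2500, length.out = 100)
  P <- matrix(0, 100, 1); P[60, 1] <- 1   # single spike
  m <- new("PCAModel", center = rep(0, 100), loadings = P,
           scores = matrix(0, 5, 1), r2x = 1, r2xCum = 1, totalSS = 1,
           wavelengths = wl)
  lw <- loadingsLinePlotData(m, 1, window_nm = 300)
  expect_true(lw$window[1] <= wl[60] && wl[60] <= lw$window[2])
  expect_true(lw$informative)

  # exhaustive-search oracle on a random loading vector
  set.seed(53)
  P2 <- matrix(rnorm(100), 100, 1); P2 <- P2 / sqrt(sum(P2^2))
  m2 <- new("PCAModel", center = rep(0, 100), loadings = P2,
            scores = matrix(0, 5, 1), r2x = 1, r2xCum = 1, totalSS = 1,
            wavelengths = wl)
  lw2 <- loadingsLinePlotData(m2, 1, window_nm = 300)
  best <- -Inf; best_win <- NULL
  for (i in seq_along(wl)) {
    j <- max(which(wl <= wl[i] + 300))
    mm <- mean(abs(P2[i:j, 1]))
    if (mm > best + 1e-15) { best <- mm; best_win <- c(wl[i], wl[j]) }
  }
  expect_equal(lw2$window, best_win)
  expect_equal(lw2$window_mean_abs, best)

  # flat loadings -> first window, flagged non-informative
  P3 <- matrix(1 / 10, 100, 1)
  m3 <- new("PCAModel", center = rep(0, 100), loadings = P3,
            scores = matrix(0, 5, 1), r2x = 1, r2xCum = 1, totalSS = 1,
            wavelengths = wl)
  lw3 <- loadingsLinePlotData(m3, 1, window_nm = 300)
  expect_false(lw3$informative)
  expect_equal(lw3$window[1], wl[1])
})

test_that("cross-validated component selection finds exact rank and floors
           at one for pure noise", {
  set.seed(54)
  T2 <- matrix(rnorm(60 * 2), 60, 2) %*% diag(c(4, 2))
  P2 <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  X2 <- tcrossprod(T2, P2)
  expect_equal(selectNComponents(X2, max_A = 6, seed = 3), 2L)

  noise <- rand_matrix(60, 20, seed = 55)
  expect_equal(selectNComponents(noise, max_A = 6, seed = 3), 1L)
  expect_lte(selectNComponents(X2, max_A = 1, seed = 3), 1L)
})
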