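test_that("wavelength cropping keeps exactly the bands above the cut", {
  wl <- c(920, 996, 1002)
  X <- matrix(1:6, 2, 3)
  cr <- cropWavelengths(X, wl, 996)
  expect_equal(cr$wavelengths, 1002)       # the boundary band 996 is removed
  expect_equal(cr$spectra, X[, 3, drop = FALSE])

  # below-grid cut is the identity
  cr2 <- cropWavelengths(X, wl, 900)
  expect_equal(cr2$wavelengths, wl)
  expect_error(cropWavelengths(X, wl, 2000), "every band")

  # brute-force count oracle on a random grid
  set.seed(4)
  wlr <- sort(runif(40, 900, 2500))
  for (cut in c(950, 1500, 2400)) {
    n_keep <- sum(vapply(wlr, function(w) w > cut, logical(1)))
    expect_equal(length(cropWavelengths(NULL, wlr, cut)$wavelengths), n_keep)
  }
})

test_that("SNV standardizes rows with sample SD and flags constants", {
  expect_equal(as.vector(snv(matrix(c(1, 2, 3), 1, 3))), c(-1, 0, 1))
  out <- snv(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(out[2, ], c(0, 0, 0))
  expect_equal(attr(out, "flagged"), 2L)
})

test_that("SNV is affine-invariant and idempotent", {
  set.seed(10)
  X <- matrix(rnorm(40 * 25), 40, 25)
  a <- runif(40, 0.5, 2); b <- rnorm(40)
  expect_equal(snv(X * a + b), snv(X), ignore_attr = TRUE, tolerance = 1e-10)
  s1 <- snv(X)
  expect_equal(snv(s1), s1, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("MSC matches a per-row least-squares oracle", {
  set.seed(11)
  ref <- rnorm(20)
  X <- rbind(2 * ref + 3,           # exact model case -> recovers ref
             ref,                   # identity
             1.3 * ref - 0.7 + rnorm(20, 0, 0.05))
  out <- msc(X, reference = ref)
  expect_equal(out[1, ], ref, tolerance = 1e-12)
  expect_equal(out[2, ], ref, tolerance = 1e-12)
  # oracle: lm fit per row
  fit <- lm(X[3, ] ~ ref)
  expect_equal(out[3, ], (X[3, ] - coef(fit)[1]) / coef(fit)[2],
               ignore_attr = TRUE, tolerance = 1e-10)
  # mean reference default
  out2 <- msc(X)
  expect_equal(attr(out2, "reference"), colMeans(X))
})

test_that("Savitzky-Golay derivative is exact on polynomials and matches a
           local polyfit oracle", {
  x <- seq_len(31)
  lin <- matrix(2.5 * x - 1, 1)
  d1 <- savgolDerivative(lin, window = 7, polyorder = 2, deriv = 1)
  expect_equal(as.vector(d1), rep(2.5, 31), tolerance = 1e-10)  # edges included
  expect_equal(as.vector(savgolDerivative(matrix(1, 1, 31), 7, 2, 1)),
               rep(0, 31), tolerance = 1e-12)

  set.seed(12)
  row <- matrix(rnorm(41), 1)
  sg <- savgolDerivative(row, window = 9, polyorder = 3, deriv = 2)
  for (j in c(5, 13, 21, 30, 37)) {   # interior positions
    xs <- ((j - 4):(j + 4)) - j       # offsets centered on the output point
    fit <- lm(row[1, j + xs] ~ poly(xs, 3, raw = TRUE))
    expect_equal(sg[1, j], 2 * coef(fit)[3], ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  expect_error(savgolDerivative(row, window = 8, polyorder = 2, deriv = 1), "odd")
  expect_error(savgolDerivative(row, window = 43, polyorder = 2, deriv = 1),
               "band count")
})

test_that("interior Savitzky-Golay values agree with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(13)
  row <- matrix(rnorm(50), 1)
  ours <- savgolDerivative(row, window = 11, polyorder = 2, deriv = 1)
  ref <- signal::sgolayfilt(row[1, ], p = 2, n = 11, m = 1)
  expect_equal(ours[1, 6:45], ref[6:45], tolerance = 1e-8)
})

test_that("mean centering stores and replays its means", {
  set.seed(14)
  X <- matrix(rnorm(30 * 8, mean = 5), 30, 8)
  out <- meanCenter(X)
  expect_lt(max(abs(colMeans(out))), 1e-10)
  mu <- attr(out, "columnMeans")
  expect_equal(meanCenter(X, means = mu), out, ignore_attr = TRUE)
  # centering disjoint halves with the full-matrix means re-concatenates
  h1 <- meanCenter(X[1:15, ], means = mu)
  h2 <- meanCenter(X[16:30, ], means = mu)
  expect_equal(rbind(h1, h2), out, ignore_attr = TRUE)
  # idempotence
  expect_equal(meanCenter(out), out, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("plan validity enforces step ordering and savgol parameters", {
  expect_error(new("PreprocessPlan",
                   steps = list(list(type = "mean_center"), list(type = "snv"))),
               "last step")
  expect_error(new("PreprocessPlan",
                   steps = list(list(type = "snv"),
                                list(type = "crop_wavelengths", min_nm = 996))),
               "first step")
  expect_error(preprocessPlan(derivative = list(window = 8, polyorder = 2,
                                                deriv = 1)), "odd")
  expect_s4_class(preprocessPlan(crop_min_nm = 996, scatter = "msc",
                                 derivative = list(window = 11, polyorder = 2,
                                                   deriv = 1)),
                  "PreprocessPlan")
})

test_that("a fitted pipeline replays identically on new pixels", {
  set.seed(15)
  wl <- seq(920, 2514, length.out = 60)
  X <- matrix(rnorm(40 * 60, mean = 1), 40, 60)
  plan <- preprocessPlan(crop_min_nm = 996, scatter = "msc",
                         derivative = list(window = 7, polyorder = 2, deriv = 1))
  fp <- fitPreprocess(plan, X, wl)
  # replaying the training matrix reproduces the fitted output
  expect_equal(applyPreprocess(fp$state, X), fp$spectra, ignore_attr = TRUE)
  # stored state (MSC reference, means) is used for new pixels: a new pixel
  # equal to a training pixel maps to the same row
  Xnew <- X[c(3, 17), , drop = FALSE]
  expect_equal(applyPreprocess(fp$state, Xnew), fp$spectra[c(3, 17), ],
               ignore_attr = TRUE)
  expect_equal(wavelengths(fp$state), wl[wl > 996])
  expect_error(applyPreprocess(fp$state, X[, 1:30]), "bands")
})
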