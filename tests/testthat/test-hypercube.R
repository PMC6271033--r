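test_that("Hypercube validity enforces its invariants", {
  a <- array(runif(8), c(2, 2, 2))
  expect_error(Hypercube(a, c(1000, 900)), "increasing")
  expect_error(Hypercube(a, c(1000, NA)), "finite")
  expect_error(Hypercube(a, 1000), "band dimension")
  expect_error(Hypercube(a * 10, c(1000, 1100), signalKind = "reflectance"),
               "reflectance")
  expect_s4_class(Hypercube(a, c(1000, 1100), signalKind = "reflectance"),
                  "Hypercube")
})

test_that("reflectance calibration follows (raw - dark)/(white - dark)", {
  nb <- 3
  dark <- rep(100, nb); white <- rep(1100, nb)
  refs <- ReferencePair(dark = dark, white = white)
  wl <- c(1000, 1500, 2000)
  raw <- Hypercube(array(600, c(1, 1, nb)), wl)
  R <- calibrateReflectance(raw, refs)
  expect_equal(as.vector(cubeData(R)), rep(0.5, nb))
  expect_identical(signalKind(R), "reflectance")

  # raw == white -> R = 1 -> A = 0; raw == dark -> floor eps -> A = 6
  white_raw <- Hypercube(array(1100, c(1, 1, nb)), wl)
  expect_equal(as.vector(cubeData(calibrateReflectance(white_raw, refs))),
               rep(1, nb))
  dark_raw <- Hypercube(array(100, c(1, 1, nb)), wl)
  A <- toPseudoAbsorbance(calibrateReflectance(dark_raw, refs))
  expect_equal(as.vector(cubeData(A)), rep(6, nb))
})

test_that("calibration errors name the offending band", {
  wl <- c(1000, 1500, 2000)
  refs <- ReferencePair(dark = c(100, 200, 100), white = c(1100, 150, 1100))
  raw <- rand_cube(2, 2, 3, kind = "raw_counts")
  expect_error(calibrateReflectance(raw, refs), "band 2")
})

test_that("cube-form references are averaged spatially before use", {
  wl <- c(1000, 1500)
  set.seed(9)
  dk <- Hypercube(array(100 + rnorm(2 * 3 * 2), c(2, 3, 2)), wl)
  wt <- Hypercube(array(1100 + rnorm(2 * 3 * 2), c(2, 3, 2)), wl)
  dkb <- apply(cubeData(dk), 3, mean); wtb <- apply(cubeData(wt), 3, mean)
  raw <- Hypercube(array(700, c(1, 1, 2)), wl)
  R <- calibrateReflectance(raw, ReferencePair(dk, wt))
  expect_equal(as.vector(cubeData(R)), (700 - dkb) / (wtb - dkb))
})

test_that("pseudo-absorbance is log10(1/R), monotone decreasing in R", {
  wl <- c(1000, 1100)
  R <- Hypercube(array(c(1, 0.5, 0.25, 0.1), c(2, 1, 2)), wl,
                 signalKind = "reflectance")
  A <- toPseudoAbsorbance(R)
  expect_equal(as.vector(cubeData(A)), -log10(c(1, 0.5, 0.25, 0.1)))
  expect_equal(cubeData(A)[1, 1, 1], 0)
  expect_equal(cubeData(A)[2, 1, 1], log10(2), tolerance = 1e-12)
  # monotonicity over a random reflectance grid
  r <- sort(runif(50, 0.01, 1.4))
  a <- -log10(r)
  expect_true(all(diff(a) < 0))
  expect_error(toPseudoAbsorbance(A), "expects a reflectance cube")
})

test_that("region spectra extraction matches a brute-force pixel scan", {
  cube <- rand_cube(10, 12, 4, seed = 21)
  set.seed(22)
  keep <- matrix(runif(120) > 0.3, 10, 12)
  keep[1:5, 1:5] <- TRUE  # guarantee >= 1% kept and a populated disk
  mask <- PixelMask(keep)
  layout <- RegionLayout(label = c("rect1", "disk1"),
                         class_hint = c("A", "B"),
                         shape = c("rect", "disk"),
                         params = list(c(2, 3, 7, 9), c(3, 3, 2.5)))
  ext <- extractRegionSpectra(cube, layout, mask)

  # brute force membership count (0-based coords, half-open rect, disk <= r)
  n_expect <- 0
  for (y in 0:9) for (x in 0:11) {
    if (!keep[y + 1, x + 1]) next
    if (y >= 2 && y < 7 && x >= 3 && x < 9) n_expect <- n_expect + 1
    if ((y - 3)^2 + (x - 3)^2 <= 2.5^2) n_expect <- n_expect + 1
  }
  expect_equal(nrow(ext$spectra), n_expect)
  # rows carry back-mappable coordinates
  i <- 5
  px <- cubeData(cube)[ext$coords$y[i] + 1, ext$coords$x[i] + 1, ]
  expect_equal(ext$spectra[i, ], px)
})

test_that("degenerate regions behave as specified", {
  cube <- rand_cube(8, 8, 3, seed = 30)
  keep <- matrix(TRUE, 8, 8); keep[5:8, ] <- FALSE
  mask <- PixelMask(keep)
  # radius-0 disk on a kept pixel -> exactly 1 row
  lay1 <- RegionLayout("p", "A", "disk", list(c(2, 2, 0)))
  expect_equal(nrow(extractRegionSpectra(cube, lay1, mask)$spectra), 1L)
  # rectangle entirely in the masked-out zone -> 0 rows + warning
  lay2 <- RegionLayout("r", "A", "rect", list(c(5, 0, 8, 8)))
  expect_warning(ext <- extractRegionSpectra(cube, lay2, mask), "no kept pixels")
  expect_equal(nrow(ext$spectra), 0L)
})

test_that("region layout CSV round-trips", {
  lay <- RegionLayout(label = c("a", "b"), class_hint = c("X", NA),
                      shape = c("rect", "disk"),
                      params = list(c(0, 0, 4, 5), c(10.5, 11, 3)))
  p <- file.path(tempdir(), "layout.csv")
  writeRegionLayout(lay, p)
  back <- readRegionLayout(p)
  expect_equal(regionTable(back), regionTable(lay))
  expect_error(RegionLayout(c("a", "a"), NA, "rect",
                            list(c(0, 0, 1, 1), c(0, 0, 1, 1))), "unique")
})
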