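snv_angle <- function(lib, a, b, wl = defaultWavelengthGrid()) {
  u <- as.vector(snv(matrix(endmemberSpectrum(lib[[a]], wl), 1), tol = 0))
  v <- as.vector(snv(matrix(endmemberSpectrum(lib[[b]], wl), 1), tol = 0))
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
}

test_that("the endmember library encodes the expected chemistry structure", {
  lib <- defaultEchinaceaLibrary()
  wl <- defaultWavelengthGrid()
  # E. pallida is the most distinct species, roots more separated than leaves
  for (organ in c("root", "leaf")) {
    ap <- snv_angle(lib, paste0("ang_", organ), paste0("purp_", organ))
    pa <- snv_angle(lib, paste0("pall_", organ), paste0("ang_", organ))
    pp <- snv_angle(lib, paste0("pall_", organ), paste0("purp_", organ))
    expect_gt(pa, ap)
    expect_gt(pp, ap)
  }
  expect_gt(snv_angle(lib, "ang_root", "purp_root"),
            snv_angle(lib, "ang_leaf", "purp_leaf"))

  # background has the lowest mean absorbance of all materials
  means <- vapply(lib, function(e) mean(endmemberSpectrum(e, wl)), numeric(1))
  expect_true(all(means["stage"] < means[names(means) != "stage"]))

  # all band centers lie on the grid, discriminating bands in 1937-2400 nm
  for (e in lib) {
    if (nrow(e$bands) == 0) next
    expect_true(all(e$bands$center >= min(wl) & e$bands$center <= max(wl)))
    sigb <- e$bands[e$bands$sig, ]
    if (nrow(sigb))
      expect_true(all(sigb$center >= 1937 & sigb$center <= 2400))
  }
})

test_that("a noiseless pure well inverts exactly through the calibration path", {
  lib <- defaultEchinaceaLibrary()
  nz <- list(sigma_m = 0, sigma_a = 0, sigma_e = 0, sigma_s = 0)
  sc <- small_scene(seed = 70, noise = nz)
  absorb <- toPseudoAbsorbance(calibrateReflectance(sc$raw, sc$refs))
  ext <- extractRegionSpectra(absorb, sc$truth$layout)
  target <- endmemberSpectrum(lib$ang_root, wavelengths(absorb))
  rows <- ext$spectra[ext$label == "ang_root_w", , drop = FALSE]
  expect_lt(max(abs(sweep(rows, 2, target, "-"))), 1e-10)
})

test_that("rendering is deterministic given the seed", {
  s1 <- small_scene(seed = 71)
  s2 <- small_scene(seed = 71)
  s3 <- small_scene(seed = 72)
  expect_identical(cubeData(s1$raw), cubeData(s2$raw))
  expect_identical(s1$truth$classMap, s2$truth$classMap)
  expect_false(identical(cubeData(s1$raw), cubeData(s3$raw)))
})

test_that("SNV of a noisy pure-well mean spectrum tracks its endmember", {
  lib <- defaultEchinaceaLibrary()
  sc <- small_scene(seed = 73)
  absorb <- toPseudoAbsorbance(calibrateReflectance(sc$raw, sc$refs))
  ext <- extractRegionSpectra(absorb, sc$truth$layout)
  for (em in c("purp_root", "pall_leaf")) {
    mean_spec <- colMeans(ext$spectra[ext$label == paste0(em, "_w"), ,
                                      drop = FALSE])
    a <- as.vector(snv(matrix(mean_spec, 1)))
    b <- as.vector(snv(matrix(endmemberSpectrum(lib[[em]],
                                                wavelengths(absorb)), 1)))
    expect_gt(cor(a, b), 0.99)
  }
})

test_that("overlapping wells are rejected", {
  wells <- list(list(cy = 20, cx = 20, r = 8, label = "w1", material = "ang_root"),
                list(cy = 24, cx = 24, r = 8, label = "w2", material = "purp_root"))
  expect_error(renderScene(sceneSpec(wells, shape = c(64L, 64L))), "overlap")
})

test_that("mixture weights are validated and remainders become excipient", {
  wells <- list(list(cy = 20, cx = 20, r = 6, label = "w", class_hint = NA,
                     material = c(ang_root = 0.25)))
  sc <- renderScene(sceneSpec(wells, shape = c(48L, 48L), seed = 5))
  comp <- sc$truth$composition
  expect_equal(comp$E_angustifolia, 0.25)
  expect_equal(comp$excipient, 0.75)
  expect_error(sceneSpec(list(list(cy = 1, cx = 1, r = 1, label = "x",
                                   material = c(ang_root = 1.2)))), "sum <= 1")
})

test_that("the study replica has the study's layout and coherent truth", {
  rep <- makeStudyReplica(seed = 3)
  expect_equal(length(rep$calibration$truth$layout), 18L)
  expect_equal(length(rep$products$truth$layout), 24L)
  comp_cal <- rep$calibration$truth$composition
  comp_pr <- rep$products$truth$composition
  cls <- c("E_angustifolia", "E_purpurea", "E_pallida", "excipient")
  expect_equal(unname(rowSums(comp_cal[, cls])), rep(1, 18))
  expect_equal(unname(rowSums(comp_pr[, cls])), rep(1, 24))
  # calibration scene: 3 species x 2 organs x 3 replicates
  expect_equal(as.integer(table(comp_cal$class_hint)), rep(6L, 3))
  expect_equal(as.integer(table(comp_cal$organ)), rep(9L, 2))
  # five extract-like products, three two-species blends
  expect_equal(sum(comp_pr$excipient == 1), 5L)
  n_two <- sum(rowSums(comp_pr[, cls[1:3]] > 0) == 2 & comp_pr$excipient == 0)
  expect_equal(n_two, 3L)
})

test_that("SNV improves class separability over raw absorbance pixels", {
  sc <- small_scene(seed = 74)
  absorb <- toPseudoAbsorbance(calibrateReflectance(sc$raw, sc$refs))
  ext <- extractRegionSpectra(absorb, sc$truth$layout)
  plan_snv <- preprocessPlan(crop_min_nm = 996, scatter = "snv")
  plan_raw <- preprocessPlan(crop_min_nm = 996, scatter = "none")
  sil_snv <- planSeparation(plan_snv, ext$spectra, ext$class_hint,
                            ext$wavelengths, maxPixels = 360, seed = 9)
  sil_raw <- planSeparation(plan_raw, ext$spectra, ext$class_hint,
                            ext$wavelengths, maxPixels = 360, seed = 9)
  expect_gt(sil_snv, sil_raw)
})
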