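#' @include synthetic.R
NULL

.CONFIG_SCHEMA <- list(
  schema_version = 1L,
  simulation = c("preset", "seed", "noise"),
  input = c("scene_header", "dark_header", "white_header", "layout_csv"),
  predict_input = c("scene_header", "dark_header", "white_header", "layout_csv"),
  preprocess = c("crop_min_nm", "scatter", "derivative", "mean_center"),
  masking = c("erode_iterations", "background"),
  pca = c("max_components", "delta"),
  plsda = c("max_factors", "delta", "min_cut", "max_cut", "cv_seed", "n_segments"),
  split = c("seed"),
  output_dir = NULL)

#' Build a validated run configuration
#'
#' Central parameter block for [runTrain()] / [runPredict()] /
#' [runReplicate()]. Unknown keys raise an error (catching config typos);
#' cut-offs are checked at construction time.
#'
#' @param simulation NULL, or list(preset = "study_replica", seed = int,
#'   noise = optional noise list) to simulate the input scenes.
#' @param input,predict_input NULL, or lists of ENVI/CSV paths
#'   (scene_header, dark_header, white_header, layout_csv) for measured
#'   training / prediction scenes.
#' @param preprocess preprocessing options (crop_min_nm, scatter,
#'   derivative, mean_center); see [preprocessPlan()].
#' @param masking masking options (erode_iterations, background).
#' @param pca PCA options (max_components, delta).
#' @param plsda PLS-DA options (max_factors, delta, min_cut, max_cut,
#'   cv_seed, n_segments).
#' @param split list(seed) for the stratified calibration/test well split.
#' @param output_dir where artifacts are written (default tempdir()).
#' @return a validated config list (class `hsichem_config`).
#' @export
runConfig <- function(simulation = list(preset = "study_replica", seed = 1),
                      input = NULL, predict_input = NULL,
                      preprocess = list(), masking = list(), pca = list(),
                      plsda = list(), split = list(),
                      output_dir = file.path(tempdir(), "hsichem_run")) {
  cfg <- list(schema_version = 1L, simulation = simulation, input = input,
              predict_input = predict_input,
              preprocess = utils::modifyList(
                list(crop_min_nm = 996, scatter = "snv", derivative = NULL,
                     mean_center = TRUE), preprocess),
              masking = utils::modifyList(
                list(erode_iterations = 1L, background = "low"), masking),
              pca = utils::modifyList(
                list(max_components = 8L, delta = 0.01), pca),
              plsda = utils::modifyList(
                list(max_factors = 8L, delta = 0.01, min_cut = 0.5,
                     max_cut = 1.5, cv_seed = 1L, n_segments = 7L), plsda),
              split = utils::modifyList(list(seed = 1L), split),
              output_dir = output_dir)
  .validate_config(cfg)
  structure(cfg, class = "hsichem_config")
}

.validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("simulation", "input", "predict_input", "preprocess",
                "masking", "pca", "plsda", "split")) {
    if (is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), .CONFIG_SCHEMA[[blk]])
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  if (cfg$plsda$min_cut >= cfg$plsda$max_cut)
    stop("plsda: min_cut must be < max_cut")
  if (is.null(cfg$simulation) && is.null(cfg$input))
    stop("config must provide either simulation or input paths")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' The file must declare `schema_version: 1`; unknown keys are errors.
#'
#' @param path YAML file path.
#' @return validated config (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != 1L)
    stop("config must declare schema_version: 1")
  y$schema_version <- NULL
  unknown <- setdiff(names(y), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, y)
}

# simulate or load the (scene, refs, layout) triple
.load_scene <- function(cfg, which = c("train", "predict")) {
  which <- match.arg(which)
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    if (!identical(sim$preset, "study_replica"))
      stop("unknown simulation preset: ", sim$preset)
    rep <- makeStudyReplica(seed = sim$seed %||% 1,
                            noise = sim$noise %||% defaultSceneNoise())
    return(if (which == "train") rep$calibration else rep$products)
  }
  inp <- if (which == "train") cfg$input else (cfg$predict_input %||% cfg$input)
  raw <- readENVI(inp$scene_header)
  refs <- ReferencePair(dark = readENVI(inp$dark_header),
                        white = readENVI(inp$white_header))
  list(raw = raw, refs = refs,
       truth = list(layout = readRegionLayout(inp$layout_csv)))
}

#' Split labeled wells into calibration and test halves
#'
#' Seeded 50/50 split stratified by class; when organ information is
#' available, each half is required to contain both organs of every class
#' (redrawn until satisfied).
#'
#' @param wells data.frame with columns `region`, `class` and optionally
#'   `organ`.
#' @param seed RNG seed.
#' @return list with character vectors `calibration` and `test` (region ids).
#' @export
splitCalibrationWells <- function(wells, seed = 1) {
  withSeed(seed, {
    cal <- character(0)
    for (cl in unique(wells$class)) {
      w <- wells[wells$class == cl, , drop = FALSE]
      n_cal <- floor(nrow(w) / 2)
      for (try in 1:200) {
        pick <- sample(w$region, n_cal)
        if (is.null(wells$organ) ||
            length(unique(w$organ[w$region %in% pick])) ==
            length(unique(w$organ))) break
      }
      cal <- c(cal, pick)
    }
    list(calibration = cal, test = setdiff(wells$region, cal))
  })
}

.log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Train the PCA + PLS-DA pipeline on a labeled scene
#'
#' Runs the full calibration chain: scene acquisition (simulated or from
#' ENVI files), white/dark calibration to pseudo-absorbance, automated
#' masking, stratified calibration/test well split, preprocessing, NIPALS
#' PCA (with cross-validated component count and the discriminating
#' loadings window), PLS-DA with Q2Y-based factor selection, and external
#' validation on the held-out wells. Artifacts (model archive, per-factor
#' statistics table, QC log) are written to the config's output directory.
#'
#' @param config a config from [runConfig()] / [readRunConfig()].
#' @param scene optionally, a pre-rendered scene (as from [renderScene()]);
#'   overrides the config's simulation/input.
#' @return (invisibly) list: `archive` (path to model.rds), `model`
#'   ([PLSDAModel-class]), `pca`, `preprocess` state, `mask`, `split`,
#'   `validation`, `factor_table`, `loadings_window`, `log`.
#' @export
runTrain <- function(config, scene = NULL) {
  .validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)

  if (is.null(scene)) scene <- .load_scene(config, "train")
  d <- dim(scene$raw)
  log <- .log_line(log, "scene: %d x %d pixels, %d bands", d[1], d[2], d[3])

  absorb <- toPseudoAbsorbance(calibrateReflectance(scene$raw, scene$refs))
  mask <- buildPixelMask(absorb, config$masking$erode_iterations,
                         config$masking$background)
  prov <- table(maskProvenance(mask))
  log <- .log_line(log, "mask: %d kept, %d background, %d dead, %d edge",
                   sum(keepMatrix(mask)), prov["background"],
                   if ("dead" %in% names(prov)) prov[["dead"]] else 0L,
                   if ("edge" %in% names(prov)) prov[["edge"]] else 0L)

  layout <- scene$truth$layout
  ext <- extractRegionSpectra(absorb, layout, mask)
  log <- .log_line(log, "extracted %d labeled pixels from %d regions",
                   nrow(ext$spectra), length(layout))

  wells <- unique(data.frame(region = ext$label, class = ext$class_hint,
                             stringsAsFactors = FALSE))
  comp <- scene$truth$composition
  if (!is.null(comp$organ))
    wells$organ <- comp$organ[match(wells$region, comp$region)]
  split <- splitCalibrationWells(wells, config$split$seed)
  cal_rows <- ext$label %in% split$calibration
  log <- .log_line(log, "split: %d calibration wells (%d px), %d test wells (%d px)",
                   length(split$calibration), sum(cal_rows),
                   length(split$test), sum(!cal_rows))

  plan <- preprocessPlan(crop_min_nm = config$preprocess$crop_min_nm,
                         scatter = config$preprocess$scatter,
                         derivative = config$preprocess$derivative,
                         mean_center = config$preprocess$mean_center)
  fp <- fitPreprocess(plan, ext$spectra[cal_rows, , drop = FALSE],
                      ext$wavelengths)
  Xcal <- fp$spectra
  Xtest <- applyPreprocess(fp$state, ext$spectra[!cal_rows, , drop = FALSE])

  nA <- selectNComponents(Xcal, config$pca$max_components,
                          delta = config$pca$delta,
                          seed = config$plsda$cv_seed)
  pca <- fitPCA(Xcal, n_components = max(nA, 3L), wavelengths = fp$wavelengths)
  lw <- loadingsLinePlotData(pca, 1L)
  log <- .log_line(log, "PCA: %d components selected, R2Xcum(3) = %.4f; window %.0f-%.0f nm",
                   nA, pca@r2xCum[min(3L, ncol(pca@loadings))],
                   lw$window[1], lw$window[2])

  classes <- sort(unique(ext$class_hint[cal_rows]))
  Y <- encodeClasses(ext$class_hint[cal_rows], classes)
  model <- fitPLSDA(Xcal, Y, max_A = config$plsda$max_factors,
                    n_segments = config$plsda$n_segments,
                    delta = config$plsda$delta, seed = config$plsda$cv_seed)
  A <- model@nFactors
  log <- .log_line(log, "PLS-DA: %d factors, R2Xcum = %.4f, R2Ycum = %.4f, Q2Ycum = %.4f",
                   A, model@r2xCum[A], model@r2yCum[A], model@q2yCum[A])

  val <- externalValidation(model, Xtest, ext$label[!cal_rows],
                            ext$class_hint[!cal_rows],
                            config$plsda$min_cut, config$plsda$max_cut)
  log <- .log_line(log, "external validation: %d/%d test wells correct, pixel accuracy %.3f",
                   sum(val$region_summary$correct), nrow(val$region_summary),
                   val$pixel_accuracy)

  nEval <- length(model@q2yCum)
  factor_table <- data.frame(factor = seq_len(nEval),
                             r2x_cum = model@r2xCum[seq_len(nEval)],
                             r2y_cum = model@r2yCum[seq_len(nEval)],
                             q2y_cum = model@q2yCum)
  cfg_stored <- config
  cfg_stored$output_dir <- NULL  # run-local path; keep archives reproducible
  archive <- list(preprocess = fp$state, pca = pca, plsda = model,
                  classes = classes, split = split, config = cfg_stored,
                  n_pca_components = nA, loadings_window = lw$window)
  archive_path <- file.path(out_dir, "model.rds")
  saveRDS(archive, archive_path)
  utils::write.csv(factor_table, file.path(out_dir, "factor_table.csv"),
                   row.names = FALSE)
  writeLines(log, file.path(out_dir, "train_log.txt"))

  invisible(list(archive = archive_path, model = model, pca = pca,
                 preprocess = fp$state, mask = mask, split = split,
                 validation = val, factor_table = factor_table,
                 loadings_window = lw, log = log, scene = scene,
                 extraction = ext, cal_rows = cal_rows))
}

#' Predict species composition of an external scene
#'
#' Applies a trained model archive to a new scene: calibration, masking,
#' replayed preprocessing, continuous dummy-Y prediction, cut-off
#' classification and per-region composition quantification. Writes the
#' composition report CSV, the class prediction image (indexed PNG with a
#' legend CSV) and a log.
#'
#' @param config a config from [runConfig()].
#' @param archive path to a model.rds from [runTrain()], or the archive
#'   list itself.
#' @param scene optionally a pre-rendered scene; overrides config.
#' @return (invisibly) list: `report` (composition data.frame), `pred`
#'   ([ClassPredictionImage-class]), `mask`, `report_csv`, `log`.
#' @export
runPredict <- function(config, archive, scene = NULL) {
  .validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(archive)) archive <- readRDS(archive)
  log <- character(0)

  if (is.null(scene)) scene <- .load_scene(config, "predict")
  if (length(wavelengths(scene$raw)) != length(archive$preprocess@wavelengthsIn) ||
      max(abs(wavelengths(scene$raw) - archive$preprocess@wavelengthsIn)) > 1e-6)
    stop("scene wavelength grid does not match the model's; resample the ",
         "scene to the training grid before prediction")

  absorb <- toPseudoAbsorbance(calibrateReflectance(scene$raw, scene$refs))
  mask <- buildPixelMask(absorb, config$masking$erode_iterations,
                         config$masking$background)
  keep <- keepMatrix(mask)
  log <- .log_line(log, "prediction scene: %d kept pixels of %d",
                   sum(keep), length(keep))

  d <- dim(absorb)
  X <- matrix(absorb@data, d[1] * d[2], d[3])[which(keep), , drop = FALSE]
  Xp <- applyPreprocess(archive$preprocess, X)
  Yhat <- predictContinuous(archive$plsda, Xp)
  pred <- classifyPixels(archive$plsda, Yhat, mask,
                         config$plsda$min_cut, config$plsda$max_cut)
  report <- quantifyComposition(pred, scene$truth$layout)
  log <- .log_line(log, "%d regions quantified; %d dominated by no_class",
                   nrow(report), sum(report$dominant == "no_class", na.rm = TRUE))

  report_csv <- file.path(out_dir, "composition_report.csv")
  utils::write.csv(report, report_csv, row.names = FALSE)
  writePredictionPNG(pred, file.path(out_dir, "prediction.png"))
  writeLines(log, file.path(out_dir, "predict_log.txt"))
  invisible(list(report = report, pred = pred, mask = mask,
                 report_csv = report_csv, log = log, scene = scene))
}

#' Write a class prediction image as an indexed PNG with legend
#'
#' @param pred a [ClassPredictionImage-class].
#' @param path output PNG path; the legend CSV goes next to it.
#' @return invisibly, the path.
#' @export
writePredictionPNG <- function(pred, path) {
  palette <- c(masked = "#000000", no_class = "#ffe119",
               stats::setNames(c("#e6194b", "#3cb44b", "#4363d8",
                                 "#f58231", "#911eb4")[seq_along(pred@classes)],
                               pred@classes))
  lv <- pred@labels
  idx <- ifelse(is.na(lv), 1L, lv + 2L)  # 1 masked, 2 no_class, 3.. classes
  cols <- grDevices::col2rgb(palette) / 255
  img <- array(0, c(nrow(lv), ncol(lv), 3))
  for (ch in 1:3) img[, , ch] <- matrix(cols[ch, idx], nrow(lv), ncol(lv))
  png::writePNG(img, path)
  utils::write.csv(data.frame(value = names(palette), color = unname(palette)),
                   sub("\\.png$", "_legend.csv", path), row.names = FALSE)
  invisible(path)
}

#' One-command study replica: simulate, train, predict
#'
#' Chains the whole pipeline on the synthetic study replica: renders the
#' 18-well calibration scene and the 24-well product scene from `seed`,
#' trains the PCA + PLS-DA model on a stratified half of the calibration
#' wells, validates on the other half, and quantifies the product scene.
#' Everything is deterministic given (`config`, `seed`).
#'
#' @param seed master seed.
#' @param output_dir artifact directory.
#' @param config optional base config; its simulation seed and output_dir
#'   are overridden by the arguments.
#' @return (invisibly) list: `train` ([runTrain()] result), `predict`
#'   ([runPredict()] result), `config`.
#' @export
runReplicate <- function(seed = 1, output_dir = file.path(tempdir(), "replica"),
                         config = NULL) {
  if (is.null(config)) config <- runConfig()
  config$simulation <- list(preset = "study_replica", seed = seed)
  config$split <- list(seed = seed)
  config$plsda$cv_seed <- seed
  config$output_dir <- output_dir
  .validate_config(config)
  rep <- makeStudyReplica(seed = seed)
  tr <- runTrain(config, scene = rep$calibration)
  pr <- runPredict(config, archive = tr$archive, scene = rep$products)
  invisible(list(train = tr, predict = pr, config = config))
}
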