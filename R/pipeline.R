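#' Default end-to-end pipeline configuration
#'
#' A nested list mirroring the generator, segmentation, model and split
#' settings. Serialised as JSON; [validateConfig()] rejects unknown keys
#' before any stage runs.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @return named list.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(
      analyte = "pyrene",
      i_max = 3000, k_ads = 0.05, replicate_cv = 0.096, noise_sd = 4,
      baseline_coeffs = c(50, 20, -30),
      grid = list(start = 200, stop = 1800, step = 2),
      levels = defaultLevels(), replicates = 20L),
    windows = list(c(350, 405), c(410, 490), c(500, 600), c(1190, 1250)),
    feature_mode = "pca_scores",
    n_components = 16L,
    score_transform = "asinh",
    model = list(learning_rate = 2e-3, epochs = 300L, lr_halve_every = 100L,
                 patience = 0L, val_fraction = 0.2, l2_lambda = 1e-5,
                 margin = 0.05),
    plsr_components = 10L,
    split = list(train_fraction = 0.7),
    calibration = list(transform = "log10", n_blanks = 10L))
}

# recursive unknown-key check against the default template
checkKeys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(cfg))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      checkKeys(cfg[[k]], template[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' @rdname defaultConfig
#' @param config a config list to validate (unknown keys are rejected with
#'   the offending key named).
#' @export
validateConfig <- function(config) {
  checkKeys(config, defaultConfig())
  if (!config$feature_mode %in% c("pca_scores", "raw"))
    stop("feature_mode must be 'pca_scores' or 'raw'")
  if (config$split$train_fraction <= 0 || config$split$train_fraction >= 1)
    stop("split.train_fraction must be in (0, 1)")
  invisible(config)
}

#' @rdname defaultConfig
#' @param path JSON config file.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$windows <- lapply(seq_len(nrow(cfg$windows)),
                        function(i) as.numeric(cfg$windows[i, ]))
  base <- defaultConfig()
  merged <- utils::modifyList(base, cfg)
  validateConfig(merged)
}

#' @rdname defaultConfig
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

configGenerator <- function(config) {
  g <- config$generator
  lib <- switch(g$analyte, pyrene = pyreneLibrary(), r6g = r6gLibrary(),
                stop("unknown analyte: ", g$analyte))
  list(library = lib,
       response = responseModel(g$i_max, g$k_ads, g$replicate_cv, g$noise_sd,
                                g$baseline_coeffs),
       grid = acquisitionGrid(g$grid$start, g$grid$stop, g$grid$step))
}

configWindows <- function(config)
  lapply(config$windows, function(w) spectralWindow(w[1], w[2]))

#' Simulate a labelled dataset and write it to disk
#'
#' Generates the configured concentration series and writes one CSV per
#' spectrum plus a `manifest.csv` into `outDir`. Deterministic under the
#' config's master seed.
#'
#' @param config list from [defaultConfig()] / [readConfig()].
#' @param outDir output directory.
#' @return the manifest data.frame, invisibly.
#' @export
runSimulate <- function(config = defaultConfig(), outDir) {
  validateConfig(config)
  gen <- configGenerator(config)
  ds <- generateDataset(gen$library, gen$response, gen$grid,
                        levels = config$generator$levels,
                        replicates = config$generator$replicates,
                        seed = config$seed)
  message("simulate: ", ncol(ds), " spectra (seed ", config$seed, ")")
  writeSpectraSet(ds, outDir)
}

#' Run the full quantitation workflow
#'
#' Segments the spectra into the configured windows, runs per-window PCA and
#' variance-contribution region selection, trains the PCA-BP network and the
#' PLSR comparator on a stratified train split, evaluates both on the held-out
#' test split, and fits the univariate calibration with its SNR = 3 LOD.
#' Blank spectra (concentration 0 in the manifest) feed the blank-noise
#' estimate; when none are supplied they are generated from the config's
#' response model under a derived seed.
#'
#' @param config list from [defaultConfig()].
#' @param spectra optional labelled [SpectraSet-class]; when NULL the
#'   dataset is generated from the config.
#' @param manifestPath optional manifest CSV to load spectra from.
#' @param outPath optional path for the JSON report bundle.
#' @return list: the report bundle (regions, models, calibration,
#'   provenance) plus `pcabpModel`, `plsrModel` and the split objects.
#' @export
runQuantify <- function(config = defaultConfig(), spectra = NULL,
                        manifestPath = NULL, outPath = NULL) {
  validateConfig(config)
  if (is.null(spectra))
    spectra <- if (!is.null(manifestPath)) readSpectraSet(manifestPath)
               else {
                 gen <- configGenerator(config)
                 generateDataset(gen$library, gen$response, gen$grid,
                                 levels = config$generator$levels,
                                 replicates = config$generator$replicates,
                                 seed = config$seed)
               }
  conc <- concentrations(spectra)
  blanks <- spectra[, !is.na(conc) & conc == 0]
  labelled <- spectra[, !is.na(conc) & conc > 0]
  conc <- concentrations(labelled)

  windows <- configWindows(config)
  sel <- selectRegion(labelled, windows, config$n_components)
  message("region selection: ", windowLabel(sel$window), " cm-1 (",
          paste(sprintf("%s: %.3f", names(sel$contributions),
                        sel$contributions), collapse = "; "), ")")

  trainIdx <- stratifiedSplit(conc, config$split$train_fraction,
                              deriveSeed(config$seed, 11L, 3L))
  train <- labelled[, trainIdx]; test <- labelled[, !trainIdx]

  ctrl <- pcaBpControl(featureMode = config$feature_mode,
                       nComponents = config$n_components,
                       scoreTransform = config$score_transform,
                       learningRate = config$model$learning_rate,
                       epochs = config$model$epochs,
                       lrHalveEvery = config$model$lr_halve_every,
                       patience = config$model$patience,
                       valFraction = config$model$val_fraction,
                       l2Lambda = config$model$l2_lambda,
                       margin = config$model$margin,
                       seed = deriveSeed(config$seed, 13L, 1L))
  pcabp <- trainPcaBp(train, sel$window, ctrl)
  pcabpReport <- evaluateModel(pcabp, test)

  plsr <- fitPlsr(train, sel$window, config$plsr_components,
                  margin = config$model$margin)
  plsrReport <- evaluateModel(plsr, test)

  calWindow <- spectralWindow(500, 600)
  fits <- fitPeaks(labelled, calWindow)
  calTab <- calibrationTable(labelled, calWindow, fits = fits)
  cal <- fitCalibration(calTab$concentration_ppm, calTab$mean_height,
                        transform = config$calibration$transform)
  if (ncol(blanks) < 3L) {
    gen <- configGenerator(config)
    blanks <- generateDataset(gen$library, gen$response, gen$grid, levels = 0,
                              replicates = config$calibration$n_blanks,
                              seed = deriveSeed(config$seed, 17L, 1L))
  }
  # blank statistic measured at the band the calibration actually uses:
  # position/width taken from the well-determined top-level fits
  topLev <- sort(unique(fits$concentration_ppm), decreasing = TRUE)[1:3]
  strong <- fits[fits$concentration_ppm %in% topLev, ]
  blankSd <- estimateBlankNoise(blanks, calWindow,
                                center = median(strong$center),
                                fwhm = median(strong$fwhm))
  cal <- computeLod(cal, blankSd)

  report <- list(
    selected_window = windowLabel(sel$window),
    variance_contributions = as.list(sel$contributions),
    pcabp = reportAsList(pcabpReport),
    plsr = reportAsList(plsrReport),
    calibration = list(transform = cal@transform, slope = cal@slope,
                       intercept = cal@intercept, r_squared = cal@rSquared,
                       blank_noise_sd = cal@blankNoiseSd, lod_ppm = cal@lod),
    calibration_table = calTab,
    provenance = list(package_version = as.character(utils::packageVersion("sersquant")),
                      r_version = as.character(getRversion()),
                      seed = config$seed, config = config))
  if (!is.null(outPath)) {
    jsonlite::write_json(report, outPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    message("report written to ", outPath)
  }
  c(report, list(pcabpModel = pcabp, plsrModel = plsr,
                 pcabpReport = pcabpReport, plsrReport = plsrReport,
                 calibration_result = cal, train = train, test = test))
}

#' Predict concentrations for unlabelled spectra
#'
#' @param model a fitted [PcaBpModel-class] (or a model JSON path, see
#'   [readModelJson()]).
#' @param spectra a [SpectraSet-class] on a grid compatible with the model,
#'   or a manifest CSV path.
#' @param outPath optional CSV output (one prediction row per spectrum).
#' @return data.frame with columns spectrum, predicted_ppm and
#'   out_of_distribution (TRUE when the raw network output sits outside the
#'   scaler's calibrated band, e.g. for blank-like input).
#' @export
runPredict <- function(model, spectra, outPath = NULL) {
  if (is.character(model)) model <- readModelJson(model)
  if (is.character(spectra)) spectra <- readSpectraSet(spectra)
  X <- extractFeatures(model, spectra)
  raw <- nnForward(model@weights, X)$output
  m <- model@scaler@margin
  pred <- unscaleConcentration(raw, model@scaler)
  out <- data.frame(spectrum = colnames(spectra),
                    predicted_ppm = pred,
                    out_of_distribution = raw < m | raw > 1 - m)
  if (!is.null(outPath)) {
    utils::write.csv(out, outPath, row.names = FALSE, quote = FALSE)
    message("predictions written to ", outPath)
  }
  out
}

#' Serialise a trained model to a single JSON file
#'
#' The network is small enough for plain text: weights, architecture, the
#' window PCA state and the concentration scaler round-trip exactly through
#' full-precision JSON.
#'
#' @param model a [PcaBpModel-class].
#' @param path output JSON file.
#' @export
writeModelJson <- function(model, path) {
  arch <- model@architecture
  payload <- list(
    type = "PcaBpModel",
    architecture = list(conv_stages = arch@convStages,
                        dense_widths = arch@denseWidths,
                        l2_lambda = arch@l2Lambda),
    feature_mode = model@featureMode,
    score_transform = model@scoreTransform,
    window = c(model@window@low, model@window@high),
    feat_shift = model@featShift,
    feat_s0 = model@featS0,
    feat_col_scale = model@featColScale,
    scaler = list(c_min = model@scaler@cMin, c_max = model@scaler@cMax,
                  margin = model@scaler@margin),
    pca = if (is.null(model@pca)) NULL else list(
      mean = model@pca@meanVector,
      loadings = model@pca@loadings,
      explained_fraction = model@pca@explainedFraction),
    weights = lapply(model@weights, function(l) {
      out <- list(type = l$type, W = l$W, b = l$b)
      if (l$type == "conv") { out$k <- l$k; out$cin <- l$cin; out$cout <- l$cout }
      out
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (is.null(p$type) || p$type != "PcaBpModel")
    stop("not a PcaBpModel JSON: ", path)
  arch <- networkArchitecture(
    convStages = lapply(seq_len(nrow(p$architecture$conv_stages)),
                        function(i) as.numeric(p$architecture$conv_stages[i, ])),
    denseWidths = p$architecture$dense_widths,
    l2Lambda = p$architecture$l2_lambda)
  window <- spectralWindow(p$window[1], p$window[2])
  weights <- lapply(p$weights, function(l) {
    l$W <- as.matrix(l$W); l$b <- as.numeric(l$b); l
  })
  pca <- NULL
  if (!is.null(p$pca)) {
    load <- as.matrix(p$pca$loadings)
    scores <- matrix(0, 2, nrow(load))  # placeholder; scores not serialised
    pca <- methods::new("RegionPCA", window = window,
                        meanVector = as.numeric(p$pca$mean), loadings = load,
                        scores = scores,
                        explainedFraction = as.numeric(p$pca$explained_fraction),
                        varianceContribution = as.numeric(p$pca$explained_fraction)[1])
  }
  methods::new("PcaBpModel", architecture = arch, weights = weights,
               featureMode = p$feature_mode,
               scoreTransform = p$score_transform, pca = pca,
               featShift = as.numeric(p$feat_shift),
               featS0 = as.numeric(p$feat_s0),
               featColScale = as.numeric(p$feat_col_scale),
               scaler = concentrationScaler(p$scaler$c_min, p$scaler$c_max,
                                            p$scaler$margin),
               window = window, trainingLog = data.frame())
}
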