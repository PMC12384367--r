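#' Read and write spectra as two-column CSV
#'
#' Spectrum files carry two columns, `wavenumber_cm1,intensity`, with a
#' header. A manifest CSV (`path,concentration_ppm,replicate`) maps spectrum
#' files to their known concentrations; the concentration field is empty for
#' unknowns.
#'
#' @param x a one-sample [SpectraSet-class] (`writeSpectrumCsv`) or a
#'   [SpectraSet-class] (`writeSpectraSet`).
#' @param path output file.
#' @name spectrum-io
NULL

#' @rdname spectrum-io
#' @export
writeSpectrumCsv <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  if (ncol(x) != 1L) stop("writeSpectrumCsv expects a single spectrum")
  # %.17g round-trips IEEE doubles exactly through the reader
  lines <- c("wavenumber_cm1,intensity",
             sprintf("%.17g,%.17g", wavenumbers(x), intensities(x)[, 1]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname spectrum-io
#' @param concentration,replicate metadata attached to the read spectrum.
#' @export
readSpectrumCsv <- function(path, concentration = NA_real_, replicate = 1L) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("wavenumber_cm1", "intensity")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns wavenumber_cm1,intensity: ", path)
  SpectraSet(matrix(df$intensity, ncol = 1), df$wavenumber_cm1,
             concentration = concentration, replicate = replicate)
}

#' @rdname spectrum-io
#' @param dir output directory for the per-spectrum CSV files.
#' @param manifestPath path of the manifest CSV to write.
#' @return `writeSpectraSet`: the manifest data.frame, invisibly.
#' @export
writeSpectraSet <- function(x, dir, manifestPath = file.path(dir, "manifest.csv")) {
  stopifnot(is(x, "SpectraSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(colnames(x), ".csv"))
  for (i in seq_len(ncol(x))) writeSpectrumCsv(x[, i], paths[i])
  manifest <- data.frame(path = paths,
                         concentration_ppm = concentrations(x),
                         replicate = replicateIds(x))
  utils::write.csv(manifest, manifestPath, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname spectrum-io
#' @export
readManifest <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  m <- utils::read.csv(manifestPath)
  need <- c("path", "concentration_ppm", "replicate")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path,concentration_ppm,replicate")
  m
}

#' @rdname spectrum-io
#' @param baseDir directory that relative manifest paths are resolved against.
#' @return `readSpectraSet`: a [SpectraSet-class] assembled from the manifest.
#' @export
readSpectraSet <- function(manifestPath, baseDir = dirname(manifestPath)) {
  m <- readManifest(manifestPath)
  paths <- ifelse(file.exists(m$path), m$path, file.path(baseDir, m$path))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("manifest spectrum file(s) not found: ",
         paste(utils::head(m$path[missing], 3), collapse = ", "))
  first <- utils::read.csv(paths[1])
  wn <- first$wavenumber_cm1
  mat <- matrix(NA_real_, length(wn), length(paths))
  mat[, 1] <- first$intensity
  for (i in seq_along(paths)[-1]) {
    df <- utils::read.csv(paths[i])
    if (length(df$wavenumber_cm1) != length(wn) ||
        any(df$wavenumber_cm1 != wn))
      stop("spectrum grid mismatch: ", paths[i], " differs from ", paths[1])
    mat[, i] <- df$intensity
  }
  colnames(mat) <- tools::file_path_sans_ext(basename(paths))
  SpectraSet(mat, wn, concentration = m$concentration_ppm,
             replicate = m$replicate)
}
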