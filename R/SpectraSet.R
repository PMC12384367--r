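#' Construct a SpectraSet
#'
#' @param intensity numeric matrix, wavenumber x sample.
#' @param wavenumber strictly increasing numeric vector, cm^-1.
#' @param concentration per-sample concentration in ppm (NA for unknowns).
#' @param replicate per-sample replicate id.
#' @param seedUsed per-sample generator seed (NA for measured data).
#'
#' @return a [SpectraSet-class].
#' @export
SpectraSet <- function(intensity, wavenumber,
                       concentration = rep(NA_real_, ncol(intensity)),
                       replicate = seq_len(ncol(intensity)),
                       seedUsed = rep(NA_integer_, ncol(intensity))) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("nrow(intensity) must equal length(wavenumber)")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("spectrum%03d", seq_len(ncol(intensity)))
  rownames(intensity) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = as.numeric(wavenumber)),
    colData = S4Vectors::DataFrame(
      concentration_ppm = as.numeric(concentration),
      replicate = as.integer(replicate),
      seed_used = as.integer(seedUsed),
      row.names = colnames(intensity)))
  methods::new("SpectraSet", se)
}

#' @describeIn SpectraSet wavenumber axis (cm^-1).
#' @param x a SpectraSet.
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber_cm1)

#' @describeIn SpectraSet wavenumber x sample intensity matrix.
#' @export
setMethod("intensities", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @describeIn SpectraSet per-sample concentration labels (ppm).
#' @export
setMethod("concentrations", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$concentration_ppm)

#' @describeIn SpectraSet per-sample replicate ids.
#' @export
setMethod("replicateIds", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$replicate)

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  conc <- concentrations(object)
  cat("SpectraSet with", ncol(object), "spectra on",
      length(wn), "wavenumbers\n")
  cat(sprintf("  grid: %.6g..%.6g cm-1\n", min(wn), max(wn)))
  lev <- sort(unique(conc[!is.na(conc)]))
  if (length(lev))
    cat("  concentration levels (ppm):",
        paste(signif(lev, 4), collapse = ", "), "\n")
  if (anyNA(conc)) cat("  unlabelled spectra:", sum(is.na(conc)), "\n")
})
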