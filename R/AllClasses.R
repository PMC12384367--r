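#' @import methods
#' @importFrom stats coef lm mad median nlminb optim prcomp rnorm sd setNames var
NULL

#' Spectral window
#'
#' A closed interval \[low, high\] on the wavenumber axis (cm^-1). Windows are
#' always expressed in physical wavenumbers, never in grid indices, and both
#' endpoints are kept when they fall on the acquisition grid.
#'
#' @slot low,high numeric(1), window bounds in cm^-1 with \code{low < high}.
#' @export
setClass("SpectralWindow", representation(low = "numeric", high = "numeric"))

setValidity("SpectralWindow", function(object) {
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("low and high must be scalars")
  if (!is.finite(object@low) || !is.finite(object@high))
    return("window bounds must be finite")
  if (object@low >= object@high) return("low must be < high")
  TRUE
})

#' A single Raman band used by the spectrum generator
#'
#' @slot center band position in cm^-1.
#' @slot relAmplitude dimensionless relative amplitude, >= 0; the strongest
#'   band of an analyte conventionally has relAmplitude 1.
#' @slot fwhm full width at half maximum in cm^-1, > 0.
#' @export
setClass("PeakSpec", representation(center = "numeric",
                                    relAmplitude = "numeric",
                                    fwhm = "numeric"))

setValidity("PeakSpec", function(object) {
  if (object@fwhm <= 0) return("fwhm must be > 0")
  if (object@relAmplitude < 0) return("relAmplitude must be >= 0")
  TRUE
})

#' Band library of one analyte
#'
#' @slot name analyte name.
#' @slot peaks list of [PeakSpec-class] with unique centers (at least one).
#' @export
setClass("AnalyteLibrary", representation(name = "character", peaks = "list"))

setValidity("AnalyteLibrary", function(object) {
  if (length(object@peaks) < 1L) return("library needs at least one peak")
  if (!all(vapply(object@peaks, is, logical(1), "PeakSpec")))
    return("peaks must all be PeakSpec objects")
  centers <- vapply(object@peaks, slot, numeric(1), "center")
  if (anyDuplicated(centers)) return("peak centers must be unique")
  TRUE
})

#' Concentration-response model of the plasmonic substrate
#'
#' Signal amplitude follows a Langmuir adsorption isotherm,
#' A(c) = iMax * kAds * c / (1 + kAds * c): the SERS response saturates as
#' adsorption sites on the substrate fill. Replicate-to-replicate scatter is a
#' single multiplicative lognormal factor per spectrum (coefficient of
#' variation \code{replicateCv}); detector noise is additive white Gaussian.
#'
#' @slot iMax saturation amplitude in counts (> 0).
#' @slot kAds adsorption constant in 1/ppm (> 0).
#' @slot replicateCv replicate coefficient of variation, fraction >= 0.
#' @slot noiseSd additive white-noise standard deviation in counts, >= 0.
#' @slot baselineCoeffs polynomial baseline coefficients (counts), evaluated
#'   on the unit-rescaled wavenumber axis.
#' @export
setClass("ResponseModel", representation(iMax = "numeric", kAds = "numeric",
                                         replicateCv = "numeric",
                                         noiseSd = "numeric",
                                         baselineCoeffs = "numeric"))

setValidity("ResponseModel", function(object) {
  if (object@iMax <= 0) return("iMax must be > 0")
  if (object@kAds <= 0) return("kAds must be > 0")
  if (object@replicateCv < 0) return("replicateCv must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Acquisition grid of the spectrometer
#'
#' @slot start,stop grid bounds in cm^-1, start < stop.
#' @slot step grid spacing in cm^-1, > 0.
#' @export
setClass("AcquisitionGrid", representation(start = "numeric", stop = "numeric",
                                           step = "numeric"))

setValidity("AcquisitionGrid", function(object) {
  if (object@start >= object@stop) return("start must be < stop")
  if (object@step <= 0) return("step must be > 0")
  TRUE
})

#' Container for a set of SERS spectra
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' \code{"intensity"} (wavenumber x sample), wavenumbers in
#' \code{rowData()$wavenumber_cm1} and per-sample acquisition metadata
#' (\code{concentration_ppm}, \code{replicate}, \code{seed_used}) in
#' \code{colData()}.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  if (!"wavenumber_cm1" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData column 'wavenumber_cm1' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber_cm1
  if (is.unsorted(wn, strictly = TRUE))
    return("wavenumbers must be strictly increasing")
  if (!all(is.finite(SummarizedExperiment::assay(object, "intensity"))))
    return("intensities must be finite")
  TRUE
})

#' Fitted Gaussian band parameters
#'
#' Result of a four-parameter least-squares fit
#' height * exp(-(x - center)^2 / (2 sigma^2)) + offset over one spectral
#' window. The width is reported as FWHM = 2 sqrt(2 ln 2) sigma, and the area
#' identity height * FWHM * sqrt(pi / (4 ln 2)) is maintained exactly.
#'
#' @slot center fitted band position, cm^-1 (inside the window).
#' @slot height fitted band height, counts.
#' @slot fwhm fitted full width at half maximum, cm^-1.
#' @slot area analytic band area, counts * cm^-1.
#' @slot offset fitted constant baseline, counts.
#' @slot residualRms root-mean-square fit residual, counts.
#' @slot converged logical flag; FALSE marks a fit that exhausted restarts.
#' @slot window the [SpectralWindow-class] that was fitted.
#' @export
setClass("PeakFit", representation(center = "numeric", height = "numeric",
                                   fwhm = "numeric", area = "numeric",
                                   offset = "numeric", residualRms = "numeric",
                                   converged = "logical",
                                   window = "SpectralWindow"))

setValidity("PeakFit", function(object) {
  if (object@fwhm <= 0) return("fwhm must be > 0")
  expected <- object@height * object@fwhm * sqrt(pi / (4 * log(2)))
  if (abs(object@area - expected) >
      1e-9 * max(1, abs(expected)))
    return("area must equal height * fwhm * sqrt(pi/(4 ln 2))")
  if (object@center < object@window@low || object@center > object@window@high)
    return("center must lie inside the fitted window")
  TRUE
})

#' Per-window principal component analysis
#'
#' Mean-centred PCA of the spectra restricted to one window. Component signs
#' are fixed so the largest-magnitude loading entry is positive, making the
#' decomposition deterministic. The variance-contribution score of the window
#' is the explained-variance fraction of the leading component.
#'
#' @slot window the analysed [SpectralWindow-class].
#' @slot meanVector per-wavenumber mean spectrum over the window.
#' @slot loadings component x wavenumber orthonormal loading matrix.
#' @slot scores sample x component score matrix, scores = (X - mean) t(loadings).
#' @slot explainedFraction explained-variance fraction per retained component.
#' @slot varianceContribution leading component's explained fraction.
#' @export
setClass("RegionPCA", representation(window = "SpectralWindow",
                                     meanVector = "numeric",
                                     loadings = "matrix",
                                     scores = "matrix",
                                     explainedFraction = "numeric",
                                     varianceContribution = "numeric"))

setValidity("RegionPCA", function(object) {
  ef <- object@explainedFraction
  if (any(ef < -1e-12) || any(ef > 1 + 1e-9))
    return("explainedFraction entries must be in [0, 1]")
  if (sum(ef) > 1 + 1e-9)
    return("explainedFraction must sum to <= 1")
  G <- tcrossprod(object@loadings)
  if (max(abs(G - diag(nrow(G)))) > 1e-8)
    return("loading rows must be orthonormal")
  if (abs(object@varianceContribution - ef[1]) > 1e-12)
    return("varianceContribution must equal explainedFraction[1]")
  TRUE
})

#' Bijective map between concentration and the network's sigmoid output
#'
#' Concentrations spanning several decades are mapped onto (margin, 1 - margin)
#' linearly in log10(c): forward(cMin) = margin, forward(cMax) = 1 - margin.
#' The margin keeps targets away from the sigmoid asymptotes.
#'
#' @slot cMin,cMax calibrated concentration range, ppm (> 0).
#' @slot margin fraction in (0, 0.5).
#' @export
setClass("ConcentrationScaler", representation(cMin = "numeric",
                                               cMax = "numeric",
                                               margin = "numeric"))

setValidity("ConcentrationScaler", function(object) {
  if (object@cMin <= 0) return("cMin must be > 0")
  if (object@cMax <= object@cMin) return("cMax must be > cMin")
  if (object@margin <= 0 || object@margin >= 0.5)
    return("margin must be in (0, 0.5)")
  TRUE
})

#' Architecture of the convolutional regression network
#'
#' Four valid-padding 1-D convolution stages (filters, kernel) =
#' (32,4), (64,4), (128,2), (256,1), a flatten, dense layers of 400, 200, 100
#' and 50 ReLU units, and a single sigmoid output with linear (log10)
#' concentration scaling. L2 weight decay regularises all weight matrices.
#'
#' @slot convStages list of integer pairs c(filters, kernel).
#' @slot denseWidths integer vector of dense-layer widths.
#' @slot l2Lambda L2 regularisation weight, >= 0.
#' @export
setClass("NetworkArchitecture", representation(convStages = "list",
                                               denseWidths = "numeric",
                                               l2Lambda = "numeric"))

setValidity("NetworkArchitecture", function(object) {
  ok <- vapply(object@convStages, function(s)
    length(s) == 2L && all(s >= 1), logical(1))
  if (!all(ok)) return("convStages must be pairs c(filters, kernel), >= 1")
  if (any(object@denseWidths < 1)) return("denseWidths must be >= 1")
  if (object@l2Lambda < 0) return("l2Lambda must be >= 0")
  TRUE
})

#' Trained PCA-BP regression model
#'
#' Bundles the network weights with everything needed to reproduce its
#' feature pipeline: the fitted window PCA (or raw-window state), the input
#' scale, and the concentration scaler.
#'
#' @slot architecture a [NetworkArchitecture-class].
#' @slot weights list of per-layer weight/bias arrays.
#' @slot featureMode one of "pca_scores" or "raw".
#' @slot scoreTransform "asinh" (blank-shifted variance-stabilising
#'   transform of the features) or "none".
#' @slot pca the training-set [RegionPCA-class] (pca_scores mode) or NULL.
#' @slot featShift,featS0,featColScale feature-conditioning state fitted on
#'   the training set: u_j = g((f_j - shift_j) / s0) * colScale_j with
#'   g = asinh or identity.
#' @slot scaler the [ConcentrationScaler-class] used for targets.
#' @slot window the input [SpectralWindow-class].
#' @slot trainingLog data.frame with per-epoch train/validation loss.
#' @export
setClass("PcaBpModel", representation(architecture = "NetworkArchitecture",
                                      weights = "list",
                                      featureMode = "character",
                                      scoreTransform = "character",
                                      pca = "ANY",
                                      featShift = "numeric",
                                      featS0 = "numeric",
                                      featColScale = "numeric",
                                      scaler = "ConcentrationScaler",
                                      window = "SpectralWindow",
                                      trainingLog = "data.frame"))

#' Fitted partial least squares regression model
#'
#' PLS1 on the window intensities against the log10-scaled concentration
#' target; the linear comparator to the PCA-BP network.
#'
#' @slot window input [SpectralWindow-class].
#' @slot ncomp number of latent components.
#' @slot xMean feature means; @slot yMean target mean.
#' @slot coefficients regression vector on centred features.
#' @slot scaler target [ConcentrationScaler-class].
#' @export
setClass("PlsrModel", representation(window = "SpectralWindow",
                                     ncomp = "numeric",
                                     xMean = "numeric", yMean = "numeric",
                                     coefficients = "numeric",
                                     scaler = "ConcentrationScaler"))

#' Prediction-quality report
#'
#' Predicted versus true concentrations with goodness-of-fit on two axes:
#' \code{rSquared} on raw ppm and \code{rSquaredLog} on the log10 axis the
#' model natively predicts (the axis on which a 4-decade calibration is
#' usually judged). The prediction-versus-true least-squares line is reported
#' on the log10 axis.
#'
#' @slot yTrue,yPred concentration vectors, ppm.
#' @slot rSquared 1 - SS_res/SS_tot on raw ppm.
#' @slot rSquaredLog same statistic on log10 concentrations.
#' @slot rmse root-mean-square error, ppm.
#' @slot fitLineSlope,fitLineIntercept least-squares line of log10(pred) on
#'   log10(true).
#' @slot model label of the evaluated model.
#' @export
setClass("RegressionReport", representation(yTrue = "numeric",
                                            yPred = "numeric",
                                            rSquared = "numeric",
                                            rSquaredLog = "numeric",
                                            rmse = "numeric",
                                            fitLineSlope = "numeric",
                                            fitLineIntercept = "numeric",
                                            model = "character"))

setValidity("RegressionReport", function(object) {
  if (length(object@yTrue) != length(object@yPred))
    return("yTrue and yPred must have equal length")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    return("rSquared must be <= 1")
  TRUE
})

#' Univariate calibration result
#'
#' Ordinary least squares of the 586 cm^-1 band statistic on concentration
#' (optionally after a log10 axis transform), the blank-noise estimate, and
#' the SNR = 3 limit of detection.
#'
#' @slot slope,intercept calibration line (counts per transformed
#'   concentration unit; counts).
#' @slot rSquared coefficient of determination of the calibration fit.
#' @slot blankNoiseSd standard deviation of the blank statistic, counts.
#' @slot lod limit of detection, ppm (NA until [computeLod()] is applied).
#' @slot transform "linear" or "log10" concentration axis.
#' @export
setClass("CalibrationResult", representation(slope = "numeric",
                                             intercept = "numeric",
                                             rSquared = "numeric",
                                             blankNoiseSd = "numeric",
                                             lod = "numeric",
                                             transform = "character"))

setValidity("CalibrationResult", function(object) {
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    return("rSquared must be <= 1")
  if (is.finite(object@lod) && is.finite(object@slope) &&
      object@slope > 0 && object@lod < 0)
    return("lod must be >= 0 when slope > 0")
  TRUE
})
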