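#' Univariate calibration of the 586 cm^-1 band
#'
#' Ordinary least squares of the band statistic (fitted Gaussian height) on
#' concentration. For data spanning several decades the default fits
#' intensity against log10(concentration); `transform = "linear"` fits
#' against raw ppm. Slope, intercept and R^2 come from the closed-form
#' normal equations.
#'
#' @param levels concentrations, ppm (>= 3 distinct values; all > 0 for the
#'   log10 transform).
#' @param intensity band statistic per level (counts).
#' @param transform "log10" (default) or "linear" concentration axis.
#' @return a [CalibrationResult-class] (LOD not yet filled; see
#'   [computeLod()]).
#' @examples
#' fitCalibration(c(1, 2, 3), c(7, 12, 17), transform = "linear")  # slope 5
#' @export
fitCalibration <- function(levels, intensity,
                           transform = c("log10", "linear")) {
  transform <- match.arg(transform)
  if (length(levels) != length(intensity))
    stop("levels and intensity must have equal length")
  if (length(unique(levels)) < 3L)
    stop("calibration needs at least 3 distinct concentration levels")
  if (transform == "log10" && any(levels <= 0))
    stop("log10 transform requires all levels > 0")
  x <- if (transform == "log10") log10(levels) else levels
  y <- intensity
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  if (syy == 0) stop("constant intensities: R^2 is undefined")
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / syy
  methods::new("CalibrationResult", slope = slope, intercept = intercept,
               rSquared = r2, blankNoiseSd = NA_real_, lod = NA_real_,
               transform = transform)
}

#' Limit of detection at SNR = 3
#'
#' The concentration whose expected net signal equals three times the blank
#' noise standard deviation. On a linear axis LOD = 3 sigma / slope; for a
#' log10-axis calibration the 3 sigma signal level is inverted through the
#' fitted line, LOD = 10^((3 sigma - intercept)/slope).
#'
#' @param cal a [CalibrationResult-class] with positive slope.
#' @param blankNoiseSd blank-statistic standard deviation, counts (see
#'   [estimateBlankNoise()]).
#' @return the input [CalibrationResult-class] with `lod` and
#'   `blankNoiseSd` filled.
#' @examples
#' cal <- fitCalibration(c(1, 2, 3), c(3, 6, 9), transform = "linear")
#' lod(computeLod(cal, 1))  # 1 ppm
#' @export
computeLod <- function(cal, blankNoiseSd) {
  stopifnot(is(cal, "CalibrationResult"))
  if (cal@slope <= 0) stop("non-positive calibration slope: no sensitivity")
  if (blankNoiseSd < 0) stop("blankNoiseSd must be >= 0")
  if (blankNoiseSd == 0)
    warning("blank noise is zero; LOD degenerates to 0")
  cal@blankNoiseSd <- blankNoiseSd
  cal@lod <- if (cal@transform == "linear") {
    3 * blankNoiseSd / cal@slope
  } else {
    if (blankNoiseSd == 0) 0
    else 10^((3 * blankNoiseSd - cal@intercept) / cal@slope)
  }
  methods::validObject(cal)
  cal
}

#' @describeIn computeLod LOD accessor (ppm).
#' @param x a CalibrationResult.
#' @export
setMethod("lod", "CalibrationResult", function(x) x@lod)

#' @describeIn computeLod calibration R^2 accessor.
#' @export
setMethod("rSquared", "CalibrationResult", function(x) x@rSquared)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult (%s axis): I = %.4g x + %.4g, R^2 = %.4f\n",
              object@transform, object@slope, object@intercept,
              object@rSquared))
  if (is.finite(object@lod))
    cat(sprintf("  blank sd = %.4g counts -> LOD (SNR = 3) = %.3g ppm\n",
                object@blankNoiseSd, object@lod))
})

#' Relative standard deviation, percent
#'
#' 100 * sample sd / mean — the replicate-uniformity statistic of the
#' substrate (scale-invariant: rsd(k v) = rsd(v) for k > 0).
#'
#' @param values numeric vector, >= 2 values with non-zero mean.
#' @return percent.
#' @examples
#' rsd(c(9, 10, 11))  # 10
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("rsd needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("rsd is undefined for zero-mean values")
  100 * sd(values) / m
}

#' Per-level calibration table
#'
#' Mean, sd and n of the fitted band height per concentration level —
#' the table behind the univariate calibration curve.
#'
#' @param spectra labelled [SpectraSet-class].
#' @param window quantitation window (default 500-600 cm^-1).
#' @param fits optional precomputed [fitPeaks()] data.frame for `spectra`.
#' @return data.frame with columns concentration_ppm, mean_height, sd_height, n.
#' @export
calibrationTable <- function(spectra, window = spectralWindow(500, 600),
                             fits = fitPeaks(spectra, window)) {
  agg <- split(fits$height, fits$concentration_ppm)
  lev <- as.numeric(names(agg))
  out <- data.frame(concentration_ppm = lev,
                    mean_height = vapply(agg, mean, numeric(1)),
                    sd_height = vapply(agg, sd, numeric(1)),
                    n = vapply(agg, length, numeric(1)))
  out[order(out$concentration_ppm), , drop = FALSE]
}
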