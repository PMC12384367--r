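#' Fit a single Gaussian band in a spectral window
#'
#' Least-squares fit of height * exp(-(x - center)^2 / (2 sigma^2)) + offset
#' over the window, by bounded quasi-Newton minimisation with analytic
#' gradients. The constant offset absorbs any flat baseline, so the fit is
#' invariant to adding a constant to the spectrum. Width is reported as
#' FWHM = 2 sqrt(2 ln 2) sigma and area as height * FWHM * sqrt(pi/(4 ln 2)).
#'
#' Initialisation: center at the window argmax, height at max - min, FWHM at
#' a quarter of the window width; on non-convergence up to 5 restarts with
#' deterministically jittered centers are attempted. A fit that exhausts all
#' restarts is returned with `converged = FALSE` rather than raising.
#'
#' @param spectrum a one-sample [SpectraSet-class] (use [fitPeaks()] for a
#'   whole set).
#' @param window the [SpectralWindow-class] to fit in (>= 5 grid points).
#' @param init optional [PeakFit-class] supplying starting values.
#' @return a [PeakFit-class].
#' @examples
#' sp <- generateSpectrum(pyreneLibrary(), responseModel(noiseSd = 0),
#'                        acquisitionGrid(), 10, seed = 1)
#' fitGaussianPeak(sp, spectralWindow(500, 600))
#' @export
fitGaussianPeak <- function(spectrum, window, init = NULL) {
  stopifnot(is(spectrum, "SpectraSet"), is(window, "SpectralWindow"))
  if (ncol(spectrum) != 1L)
    stop("fitGaussianPeak expects a single spectrum; see fitPeaks()")
  sub <- cropWindow(spectrum, window)
  x <- wavenumbers(sub)
  y <- intensities(sub)[, 1]
  if (length(x) < 5L)
    stop("window ", windowLabel(window), " contains fewer than 5 points")
  if (max(y) == min(y))
    stop("degenerate flat window ", windowLabel(window), ": nothing to fit")

  width <- window@high - window@low
  step <- min(diff(x))
  fwhmToSigma <- 1 / (2 * sqrt(2 * log(2)))
  # normalise the intensity scale so the optimiser sees O(1) parameters
  # whatever the counts; results are mapped back afterwards
  yShift <- min(y)
  yScale <- max(y) - min(y)
  y <- (y - yShift) / yScale
  # theta = (center, height, sigma, offset)
  start <- if (!is.null(init)) {
    c(init@center, (init@height) / yScale, init@fwhm * fwhmToSigma,
      (init@offset - yShift) / yScale)
  } else {
    c(x[which.max(y)], 1, (width / 4) * fwhmToSigma, 0)
  }
  lower <- c(window@low, 0, step / 4, -Inf)
  upper <- c(window@high, Inf, 2 * width, Inf)

  sse <- function(th) {
    g <- exp(-(x - th[1])^2 / (2 * th[3]^2))
    sum((th[2] * g + th[4] - y)^2)
  }
  sseGrad <- function(th) {
    d <- x - th[1]
    g <- exp(-d^2 / (2 * th[3]^2))
    r <- th[2] * g + th[4] - y
    c(sum(2 * r * th[2] * g * d / th[3]^2),
      sum(2 * r * g),
      sum(2 * r * th[2] * g * d^2 / th[3]^3),
      sum(2 * r))
  }

  jitters <- c(0, -0.25, 0.25, -0.1, 0.1) * width
  best <- NULL
  converged <- FALSE
  for (j in jitters) {
    s <- start
    s[1] <- min(max(s[1] + j, window@low), window@high)
    fit <- tryCatch(
      nlminb(s, sse, gradient = sseGrad, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000,
                            rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # treat a stationary point (tiny scaled gradient) as converged even when
    # nlminb labels it singular/false convergence
    ok <- fit$convergence == 0 ||
      sqrt(sum(sseGrad(fit$par)^2)) <= 1e-6 * (1 + fit$objective)
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      converged <- ok
    }
    if (ok) break
  }
  if (is.null(best))
    stop("Gaussian fit failed in window ", windowLabel(window))
  th <- best$par
  fwhm <- th[3] / fwhmToSigma
  height <- th[2] * yScale
  methods::new("PeakFit",
               center = th[1], height = height, fwhm = fwhm,
               area = height * fwhm * sqrt(pi / (4 * log(2))),
               offset = th[4] * yScale + yShift,
               residualRms = sqrt(best$objective / length(x)) * yScale,
               converged = converged, window = window)
}

setMethod("show", "PeakFit", function(object) {
  cat(sprintf(paste0("PeakFit in %s cm-1: center %.2f, height %.3g, ",
                     "FWHM %.2f, area %.4g%s\n"),
              windowLabel(object@window), object@center, object@height,
              object@fwhm, object@area,
              if (object@converged) "" else " [not converged]"))
})

#' Fit the window band in every spectrum of a set
#'
#' @param spectra a [SpectraSet-class].
#' @param window the [SpectralWindow-class] to fit in.
#' @return data.frame with one row per spectrum: center, height, fwhm, area,
#'   offset, residual_rms, converged, concentration_ppm, replicate.
#' @export
fitPeaks <- function(spectra, window) {
  fits <- lapply(seq_len(ncol(spectra)), function(i)
    fitGaussianPeak(spectra[, i], window))
  data.frame(
    center = vapply(fits, slot, numeric(1), "center"),
    height = vapply(fits, slot, numeric(1), "height"),
    fwhm = vapply(fits, slot, numeric(1), "fwhm"),
    area = vapply(fits, slot, numeric(1), "area"),
    offset = vapply(fits, slot, numeric(1), "offset"),
    residual_rms = vapply(fits, slot, numeric(1), "residualRms"),
    converged = vapply(fits, slot, logical(1), "converged"),
    concentration_ppm = concentrations(spectra),
    replicate = replicateIds(spectra))
}

#' Blank-noise estimate for the SNR = 3 detection limit
#'
#' Standard deviation, across blank (analyte-free) spectra, of the signal
#' statistic used for calibration. A blank contains no band to locate, so
#' when the band position (and width) of the analyte are supplied the height
#' is measured by a linear fit of a fixed Gaussian profile plus offset —
#' the matched-filter statistic a blank actually supports. Without them the
#' full free-center fit of [fitGaussianPeak()] is used (note that fishing
#' for the best band position in pure noise inflates both the mean and the
#' spread of the statistic).
#'
#' @param blanks a [SpectraSet-class] of at least 3 blank spectra.
#' @param window the quantitation [SpectralWindow-class].
#' @param statistic "height" (fitted band height) or "max" (window maximum).
#' @param center,fwhm optional fixed band position and width (cm^-1); when
#'   both are given the height fit is linear with the profile held fixed.
#' @return numeric(1), counts.
#' @export
estimateBlankNoise <- function(blanks, window,
                               statistic = c("height", "max"),
                               center = NULL, fwhm = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is(blanks, "SpectraSet"))
  if (ncol(blanks) < 3L)
    stop("at least 3 blank spectra are required, got ", ncol(blanks))
  vals <- if (statistic == "max") {
    apply(intensities(cropWindow(blanks, window)), 2, max)
  } else if (!is.null(center) && !is.null(fwhm)) {
    sub <- cropWindow(blanks, window)
    x <- wavenumbers(sub)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    G <- cbind(height = exp(-(x - center)^2 / (2 * sigma^2)), offset = 1)
    coefs <- solve(crossprod(G), crossprod(G, intensities(sub)))
    coefs["height", ]
  } else {
    fitPeaks(blanks, window)$height
  }
  sd(vals)
}
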