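#' Band, library, response-model and grid constructors
#'
#' Small constructors for the synthetic-spectrum generator's stated world.
#'
#' @param center band position (cm^-1).
#' @param relAmplitude relative amplitude, >= 0.
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @return `peakSpec`: a [PeakSpec-class].
#' @name generator-constructors
NULL

#' @rdname generator-constructors
#' @export
peakSpec <- function(center, relAmplitude = 1, fwhm = 20)
  methods::new("PeakSpec", center = as.numeric(center),
               relAmplitude = as.numeric(relAmplitude),
               fwhm = as.numeric(fwhm))

#' @rdname generator-constructors
#' @param name analyte name.
#' @param peaks list of [PeakSpec-class].
#' @export
analyteLibrary <- function(name, peaks)
  methods::new("AnalyteLibrary", name = name, peaks = peaks)

#' Default pyrene band library
#'
#' The quantitation band of pyrene sits at 586 cm^-1 (relative amplitude 1).
#' The three weak satellite bands at 380, 455 and 1240 cm^-1 are synthetic
#' stand-ins — placed inside the non-quantitation analysis windows so that
#' region selection has realistic competition — not literature pyrene
#' assignments.
#'
#' @return an [AnalyteLibrary-class].
#' @export
pyreneLibrary <- function()
  analyteLibrary("pyrene", list(
    peakSpec(586, 1.00, 20),
    peakSpec(380, 0.22, 18),
    peakSpec(455, 0.18, 18),
    peakSpec(1240, 0.30, 22)))

#' R6G band library (308, 1194, 1360, 1508 cm^-1)
#'
#' Rhodamine 6G bands: C-O-C stretch at 308 cm^-1 and aromatic C-C stretches
#' at 1194, 1360 and 1508 cm^-1.
#'
#' @return an [AnalyteLibrary-class].
#' @export
r6gLibrary <- function()
  analyteLibrary("R6G", list(
    peakSpec(308, 0.6, 18),
    peakSpec(1194, 0.8, 18),
    peakSpec(1360, 1.0, 18),
    peakSpec(1508, 0.9, 18)))

#' @rdname generator-constructors
#' @param iMax Langmuir saturation amplitude, counts.
#' @param kAds adsorption constant, 1/ppm.
#' @param replicateCv replicate coefficient of variation (default 0.096, the
#'   replicate RSD of the plasmonic channel).
#' @param noiseSd additive white-noise sd, counts. The default (4 counts at
#'   iMax = 3000) is anchored so the univariate SNR = 3 limit of detection
#'   lands near 0.08 ppm: noiseSd ~ LOD * iMax * kAds / 3.
#' @param baselineCoeffs polynomial baseline coefficients in counts, evaluated
#'   in the unit-rescaled wavenumber t = (x - start)/(stop - start).
#' @export
responseModel <- function(iMax = 3000, kAds = 0.05, replicateCv = 0.096,
                          noiseSd = 4, baselineCoeffs = c(50, 20, -30))
  methods::new("ResponseModel", iMax = as.numeric(iMax),
               kAds = as.numeric(kAds), replicateCv = as.numeric(replicateCv),
               noiseSd = as.numeric(noiseSd),
               baselineCoeffs = as.numeric(baselineCoeffs))

#' @rdname generator-constructors
#' @param start,stop,step grid bounds and spacing, cm^-1. The default 2 cm^-1
#'   step gives the 500-600 window 51 points; `step = 5` matches the
#'   portable spectrometer's 5 cm^-1 resolution.
#' @export
acquisitionGrid <- function(start = 200, stop = 1800, step = 2)
  methods::new("AcquisitionGrid", start = as.numeric(start),
               stop = as.numeric(stop), step = as.numeric(step))

#' @describeIn generator-constructors wavenumber vector of a grid.
#' @export
setMethod("wavenumbers", "AcquisitionGrid", function(x)
  seq(x@start, x@stop, by = x@step))

#' Default concentration series, ppm
#'
#' Nine log-spaced levels spanning the 0.01-70 ppm working range.
#' @export
defaultLevels <- function() c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 30, 70)

# Langmuir adsorption amplitude at concentration c (ppm).
langmuirAmplitude <- function(response, concentration)
  response@iMax * response@kAds * concentration /
    (1 + response@kAds * concentration)

baselineValues <- function(response, grid) {
  x <- wavenumbers(grid)
  t <- (x - grid@start) / (grid@stop - grid@start)
  b <- response@baselineCoeffs
  Reduce(`+`, lapply(seq_along(b), function(j) b[j] * t^(j - 1)))
}

#' Generate one synthetic SERS spectrum
#'
#' Intensity model: baseline(x) + eps * A(c) * sum_peaks relAmplitude *
#' gauss(x; center, fwhm) + white noise, where A(c) = iMax * kAds * c /
#' (1 + kAds * c) is the Langmuir response and eps is a single per-spectrum
#' lognormal factor with CV = replicateCv (mean 1). Identical seeds give
#' identical spectra.
#'
#' @param library an [AnalyteLibrary-class].
#' @param response a [ResponseModel-class].
#' @param grid an [AcquisitionGrid-class].
#' @param concentration analyte concentration, ppm, >= 0.
#' @param seed integer seed for this spectrum.
#' @param replicate replicate id stored in the metadata.
#'
#' @return a one-sample [SpectraSet-class].
#' @export
generateSpectrum <- function(library, response, grid, concentration,
                             seed = 1L, replicate = 1L) {
  stopifnot(is(library, "AnalyteLibrary"), is(response, "ResponseModel"),
            is(grid, "AcquisitionGrid"))
  if (length(concentration) != 1L || is.na(concentration) || concentration < 0)
    stop("concentration must be a single value >= 0")
  centers <- vapply(library@peaks, slot, numeric(1), "center")
  bad <- centers < grid@start | centers > grid@stop
  if (any(bad))
    stop("peak center(s) ", paste(centers[bad], collapse = ", "),
         " cm-1 outside the acquisition grid ", grid@start, "-", grid@stop)
  x <- wavenumbers(grid)
  amp <- langmuirAmplitude(response, concentration)
  shape <- numeric(length(x))
  for (p in library@peaks) {
    sigma <- p@fwhm / (2 * sqrt(2 * log(2)))
    shape <- shape + p@relAmplitude * exp(-(x - p@center)^2 / (2 * sigma^2))
  }
  y <- withLocalSeed(seed, {
    eps <- if (response@replicateCv > 0) {
      sdlog <- sqrt(log(1 + response@replicateCv^2))
      exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
    } else 1
    noise <- if (response@noiseSd > 0)
      rnorm(length(x), 0, response@noiseSd) else 0
    baselineValues(response, grid) + eps * amp * shape + noise
  })
  SpectraSet(matrix(y, ncol = 1), x, concentration = concentration,
             replicate = replicate, seedUsed = seed)
}

#' Generate a labelled concentration series of synthetic spectra
#'
#' Emulates the stated acquisition: a 0.01-70 ppm pyrene series with 20
#' replicate spectra per level. Per-spectrum seeds are derived
#' deterministically from the master seed and the (level, replicate) index,
#' so the same master seed reproduces the dataset exactly.
#'
#' @inheritParams generateSpectrum
#' @param levels concentration levels, ppm (all >= 0, non-empty).
#' @param replicates spectra per level (>= 1, default 20).
#' @param seed master seed.
#'
#' @return a [SpectraSet-class] with `length(levels) * replicates` spectra.
#' @examples
#' ds <- generateDataset(replicates = 2, seed = 7)
#' ncol(ds)  # 18 spectra
#' @export
generateDataset <- function(library = pyreneLibrary(),
                            response = responseModel(),
                            grid = acquisitionGrid(),
                            levels = defaultLevels(),
                            replicates = 20L, seed = 1L) {
  if (length(levels) < 1L || any(is.na(levels)) || any(levels < 0))
    stop("levels must be non-empty and all >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  x <- wavenumbers(grid)
  centers <- vapply(library@peaks, slot, numeric(1), "center")
  bad <- centers < grid@start | centers > grid@stop
  if (any(bad))
    stop("peak center(s) ", paste(centers[bad], collapse = ", "),
         " cm-1 outside the acquisition grid ", grid@start, "-", grid@stop)
  # shared across spectra; per spectrum only eps and white noise are drawn,
  # exactly as in generateSpectrum and in the same RNG order
  shape <- numeric(length(x))
  for (p in library@peaks) {
    sigma <- p@fwhm / (2 * sqrt(2 * log(2)))
    shape <- shape + p@relAmplitude * exp(-(x - p@center)^2 / (2 * sigma^2))
  }
  bl <- baselineValues(response, grid)
  sdlog <- sqrt(log(1 + response@replicateCv^2))
  n <- length(levels) * replicates
  mat <- matrix(NA_real_, length(x), n)
  conc <- numeric(n); reps <- integer(n); seeds <- integer(n)
  k <- 0L
  for (i in seq_along(levels)) {
    amp <- langmuirAmplitude(response, levels[i])
    for (j in seq_len(replicates)) {
      k <- k + 1L
      s <- deriveSeed(seed, i, j)
      mat[, k] <- withLocalSeed(s, {
        eps <- if (response@replicateCv > 0)
          exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog)) else 1
        noise <- if (response@noiseSd > 0)
          rnorm(length(x), 0, response@noiseSd) else 0
        bl + eps * amp * shape + noise
      })
      conc[k] <- levels[i]; reps[k] <- j; seeds[k] <- s
    }
  }
  colnames(mat) <- sprintf("L%02dR%02d",
                           rep(seq_along(levels), each = replicates),
                           rep(seq_len(replicates), length(levels)))
  SpectraSet(mat, x, concentration = conc, replicate = reps, seedUsed = seeds)
}
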