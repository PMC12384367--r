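#' Principal component analysis of one spectral window
#'
#' Mean-centred (not variance-scaled: band height carries the signal) PCA of
#' the spectra restricted to `window`. Component signs are fixed so the
#' largest-magnitude entry of each loading vector is positive, which makes
#' the decomposition fully deterministic. The window's variance-contribution
#' score is the explained-variance fraction of the leading component.
#'
#' @param spectra a [SpectraSet-class] with >= 2 spectra.
#' @param window a [SpectralWindow-class].
#' @param nComponents number of components to retain; truncated with a
#'   warning when it exceeds the available rank.
#' @return a [RegionPCA-class].
#' @examples
#' ds <- generateDataset(replicates = 3, seed = 1)
#' fitRegionPCA(ds, spectralWindow(500, 600), 4)
#' @export
fitRegionPCA <- function(spectra, window, nComponents = 16L) {
  stopifnot(is(spectra, "SpectraSet"), is(window, "SpectralWindow"))
  if (ncol(spectra) < 2L) stop("PCA needs at least 2 spectra")
  X <- t(intensities(cropWindow(spectra, window)))  # samples x wavenumbers
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  totVar <- sum(pc$sdev^2)
  if (totVar <= 0) stop("window ", windowLabel(window), " has zero variance")
  avail <- length(pc$sdev)            # min(n samples - 1, n points)
  if (nComponents > avail) {
    warning("window ", windowLabel(window), ": requested ", nComponents,
            " components but only ", avail, " exist; truncating")
    nComponents <- avail
  }
  idx <- seq_len(nComponents)
  load <- t(pc$rotation[, idx, drop = FALSE])   # comp x wavenumber
  scores <- pc$x[, idx, drop = FALSE]
  # deterministic sign: largest-|.| loading entry positive
  for (k in idx) {
    m <- which.max(abs(load[k, ]))
    if (load[k, m] < 0) {
      load[k, ] <- -load[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  ef <- pc$sdev[idx]^2 / totVar
  methods::new("RegionPCA", window = window, meanVector = pc$center,
               loadings = load, scores = scores, explainedFraction = ef,
               varianceContribution = ef[1])
}

#' @describeIn fitRegionPCA leading-component explained-variance fraction.
#' @param x a RegionPCA.
#' @export
setMethod("varianceContribution", "RegionPCA",
          function(x) x@varianceContribution)

#' @describeIn fitRegionPCA explained-variance fractions of the retained
#'   components.
#' @export
setMethod("explainedFraction", "RegionPCA", function(x) x@explainedFraction)

#' @describeIn fitRegionPCA sample x component score matrix.
#' @export
setMethod("pcaScores", "RegionPCA", function(x) x@scores)

#' @describeIn fitRegionPCA component x wavenumber loading matrix.
#' @export
setMethod("pcaLoadings", "RegionPCA", function(x) x@loadings)

setMethod("show", "RegionPCA", function(object) {
  cat(sprintf(paste0("RegionPCA %s cm-1: %d components, variance ",
                     "contribution %.4f\n"), windowLabel(object@window),
              nrow(object@loadings), object@varianceContribution))
})

# Project new spectra onto a fitted RegionPCA: (X - mean) t(loadings).
projectRegionPCA <- function(pca, spectra) {
  X <- t(intensities(cropWindow(spectra, pca@window)))
  if (ncol(X) != length(pca@meanVector))
    stop("grid mismatch: PCA was fitted on ", length(pca@meanVector),
         " points, spectra have ", ncol(X))
  sweep(X, 2, pca@meanVector) %*% t(pca@loadings)
}

#' Select the analysis window by variance contribution
#'
#' Fits a [RegionPCA-class] in every candidate window and returns the window
#' whose leading component explains the largest fraction of that window's
#' variance. Ties are broken deterministically towards the lower wavenumber
#' bound. In the pyrene system the concentration-responsive 586 cm^-1 band
#' makes 500-600 cm^-1 the expected winner.
#'
#' @param spectra a [SpectraSet-class].
#' @param windows list of [SpectralWindow-class] (default: the four analysis
#'   windows of [defaultWindows()]).
#' @param nComponents components retained in each per-window PCA.
#' @return list with elements `window` (the selected [SpectralWindow-class]),
#'   `regions` (all per-window [RegionPCA-class] results, named by window)
#'   and `contributions` (named numeric vector).
#' @export
selectRegion <- function(spectra, windows = defaultWindows(),
                         nComponents = 16L) {
  if (length(windows) < 1L) stop("at least one window is required")
  regions <- lapply(windows, function(w) {
    nc <- min(nComponents, ncol(spectra) - 1L,
              sum(wavenumbers(spectra) >= w@low & wavenumbers(spectra) <= w@high))
    fitRegionPCA(spectra, w, nc)
  })
  labels <- vapply(windows, windowLabel, character(1))
  names(regions) <- labels
  contrib <- vapply(regions, varianceContribution, numeric(1))
  lows <- vapply(windows, slot, numeric(1), "low")
  best <- order(-contrib, lows)[1]
  list(window = windows[[best]], regions = regions, contributions = contrib)
}
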