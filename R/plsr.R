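#' Partial least squares regression comparator
#'
#' PLS1 of the window intensities against the log10-scaled concentration
#' target — the linear baseline the PCA-BP network is compared with. The
#' deflation algorithm is deterministic; for a single response it needs no
#' iteration. Predictions are mapped back to ppm through the scaler.
#'
#' @param trainSpectra labelled [SpectraSet-class].
#' @param window input [SpectralWindow-class].
#' @param nComponents latent components (<= min(n samples - 1, n features)).
#' @param margin sigmoid-margin of the shared concentration scaler (kept
#'   identical to the network's so both models predict on the same axis).
#' @return a [PlsrModel-class].
#' @examples
#' ds <- generateDataset(replicates = 4, seed = 2)
#' m <- fitPlsr(ds, spectralWindow(500, 600), 5)
#' predictConcentration(m, ds[, 1:3])
#' @export
fitPlsr <- function(trainSpectra, window = spectralWindow(500, 600),
                    nComponents = 10L, margin = 0.05) {
  conc <- concentrations(trainSpectra)
  if (anyNA(conc)) stop("all training spectra must have known concentrations")
  if (length(unique(conc)) < 2L)
    stop("training data has a single concentration level")
  X <- t(intensities(cropWindow(trainSpectra, window)))
  if (nComponents > min(nrow(X) - 1L, ncol(X)))
    stop("nComponents must be <= min(n samples - 1, n features)")
  scaler <- concentrationScaler(min(conc), max(conc), margin)
  y <- scaleConcentration(conc, scaler)

  xMean <- colMeans(X); yMean <- mean(y)
  E <- sweep(X, 2, xMean); f <- y - yMean
  p <- ncol(X)
  W <- matrix(0, p, nComponents); P <- matrix(0, p, nComponents)
  q <- numeric(nComponents)
  for (a in seq_len(nComponents)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { # residual exhausted; truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      warning("PLSR residual exhausted after ", a - 1, " components")
      break
    }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    pvec <- crossprod(E, t_) / tt
    qa <- sum(f * t_) / tt
    E <- E - t_ %*% t(pvec)
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  methods::new("PlsrModel", window = window, ncomp = ncol(W),
               xMean = xMean, yMean = yMean,
               coefficients = as.numeric(beta), scaler = scaler)
}

#' @describeIn fitPlsr predict concentrations (ppm) for new spectra.
#' @param object a fitted [PlsrModel-class].
#' @param spectra a [SpectraSet-class] on a compatible grid.
#' @param ... unused.
#' @export
setMethod("predictConcentration", "PlsrModel", function(object, spectra, ...) {
  X <- t(intensities(cropWindow(spectra, object@window)))
  if (ncol(X) != length(object@xMean))
    stop("grid mismatch: model expects ", length(object@xMean),
         " window points, spectra have ", ncol(X))
  yhat <- object@yMean + sweep(X, 2, object@xMean) %*% object@coefficients
  # keep the linear model's predictions inside the scaler's invertible band
  unscaleConcentration(as.numeric(yhat), object@scaler)
})

setMethod("show", "PlsrModel", function(object)
  cat("PlsrModel:", object@ncomp, "components on window",
      windowLabel(object@window), "cm-1\n"))
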