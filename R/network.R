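#' Construct the regression-network architecture
#'
#' Defaults follow the quantitation network: 1-D convolution stages
#' (filters, kernel) = (32,4), (64,4), (128,2), (256,1) with valid padding,
#' flatten, dense ReLU layers of 400, 200, 100, 50 units, and one sigmoid
#' output unit whose value is mapped to concentration by a
#' [ConcentrationScaler-class]. All weight matrices carry L2 decay.
#'
#' @param convStages list of c(filters, kernel) pairs.
#' @param denseWidths dense-layer widths.
#' @param l2Lambda L2 regularisation weight.
#' @return a [NetworkArchitecture-class].
#' @export
networkArchitecture <- function(convStages = list(c(32, 4), c(64, 4),
                                                  c(128, 2), c(256, 1)),
                                denseWidths = c(400, 200, 100, 50),
                                l2Lambda = 1e-4)
  methods::new("NetworkArchitecture", convStages = convStages,
               denseWidths = as.numeric(denseWidths),
               l2Lambda = as.numeric(l2Lambda))

#' Layer output shapes of an architecture
#'
#' Traverses the network symbolically: each conv stage maps
#' (length, channels) -> (length - kernel + 1, filters); the flatten and
#' dense stages follow. Errors if the sequence length underflows.
#'
#' @param arch a [NetworkArchitecture-class].
#' @param inputLength length of the input sequence (1 channel).
#' @return data.frame with columns layer, type, out_length, out_channels
#'   (dense layers report out_channels = width, out_length = NA).
#' @export
networkShapes <- function(arch, inputLength) {
  L <- inputLength; C <- 1L
  rows <- list()
  for (i in seq_along(arch@convStages)) {
    s <- arch@convStages[[i]]
    L <- L - s[2] + 1
    if (L < 1)
      stop("input length ", inputLength, " too short for conv stage ", i,
           " (kernel ", s[2], ")")
    C <- s[1]
    rows[[length(rows) + 1L]] <-
      data.frame(layer = paste0("conv", i), type = "conv1d",
                 out_length = L, out_channels = C)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "flatten", type = "flatten",
               out_length = NA_real_, out_channels = L * C)
  for (i in seq_along(arch@denseWidths))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = paste0("dense", i), type = "dense",
                 out_length = NA_real_, out_channels = arch@denseWidths[i])
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "output", type = "sigmoid",
               out_length = NA_real_, out_channels = 1)
  do.call(rbind, rows)
}

# He-normal initial weights for every layer, seeded and reproducible.
initNetworkWeights <- function(arch, inputLength, seed) {
  networkShapes(arch, inputLength)  # validates the length budget
  withLocalSeed(seed, {
    layers <- list()
    L <- inputLength; C <- 1L
    for (s in arch@convStages) {
      fanIn <- s[2] * C
      layers[[length(layers) + 1L]] <- list(
        type = "conv", k = s[2], cin = C, cout = s[1],
        W = matrix(rnorm(fanIn * s[1], sd = sqrt(2 / fanIn)), fanIn, s[1]),
        b = numeric(s[1]))
      L <- L - s[2] + 1; C <- s[1]
    }
    d <- L * C
    for (w in c(arch@denseWidths, 1)) {
      layers[[length(layers) + 1L]] <- list(
        type = "dense",
        W = matrix(rnorm(d * w, sd = sqrt(2 / d)), d, w),
        b = numeric(w))
      d <- w
    }
    layers
  })
}

# Convolution activations are held as plain n x (L*C) matrices with the
# position index fastest (channel-major columns); patches are gathered by a
# precomputed column index, which avoids 3-d array reshuffling in the hot
# training loop.

# columns of the im2col patch matrix for an (L, C) input and kernel k:
# patch column (dk, c) at output position p reads input column
# (p + dk - 1) + (c - 1) * L
convPatchIndex <- function(L, C, k) {
  Lout <- L - k + 1
  idx <- matrix(0L, Lout, k * C)
  for (p in seq_len(Lout))
    idx[p, ] <- as.integer(outer(p:(p + k - 1), (seq_len(C) - 1L) * L, "+"))
  idx
}

# A: n x (L*C) matrix -> patch matrix (n*Lout) x (k*C), sample-fastest rows
convPatches <- function(A, n, L, C, k) {
  Lout <- L - k + 1
  idx <- convPatchIndex(L, C, k)
  P <- matrix(0, n * Lout, k * C)
  for (p in seq_len(Lout))
    P[(p - 1L) * n + seq_len(n), ] <- A[, idx[p, ], drop = FALSE]
  P
}

# Forward pass over an n x d input matrix; returns n-vector of sigmoid
# outputs plus per-layer caches for backpropagation.
nnForward <- function(layers, X, keepCache = FALSE) {
  n <- nrow(X)
  A <- X                      # n x (L*C), C = 1 on input
  L <- ncol(X); C <- 1L
  cache <- if (keepCache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (C != ly$cin || L < ly$k)
        stop("shape mismatch at conv layer ", i, ": expected >= ", ly$k,
             " points x ", ly$cin, " channels, got ", L, " x ", C)
      P <- convPatches(A, n, L, C, ly$k)
      Z <- P %*% ly$W
      if (any(ly$b != 0))
        Z <- Z + rep.int(ly$b, rep.int(nrow(Z), length(ly$b)))
      H <- Z * (Z > 0)
      Lout <- L - ly$k + 1
      if (keepCache) cache[[i]] <- list(P = P, Z = Z, L = L, C = C)
      # rows (sample within position) -> columns (position within channel);
      # same column-major linear layout, so only the dim attribute changes
      dim(H) <- c(n, Lout * ly$cout)
      A <- H
      L <- Lout; C <- ly$cout
    } else {
      if (ncol(A) != nrow(ly$W))
        stop("shape mismatch at dense layer ", i, ": expected input ",
             nrow(ly$W), ", got ", ncol(A))
      Z <- A %*% ly$W
      if (any(ly$b != 0))
        Z <- Z + rep.int(ly$b, rep.int(n, length(ly$b)))
      last <- i == length(layers)
      H <- if (last) 1 / (1 + exp(-Z)) else Z * (Z > 0)
      if (keepCache) cache[[i]] <- list(A = A, Z = Z)
      A <- H
      L <- ncol(A); C <- 1L
    }
  }
  list(output = as.numeric(A), cache = cache)
}

# Mean-squared-error loss with L2 weight decay, and its exact gradient by
# backpropagation. Returns list(loss, grads) with grads mirroring `layers`.
nnLossGradient <- function(layers, X, target, l2 = 0) {
  n <- nrow(X)
  fw <- nnForward(layers, X, keepCache = TRUE)
  yhat <- fw$output
  loss <- mean((yhat - target)^2) +
    l2 * sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
  grads <- vector("list", length(layers))
  # output layer: d loss / d z = 2 (yhat - t)/n * sigmoid'
  delta <- matrix(2 * (yhat - target) / n * yhat * (1 - yhat), n, 1)
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- fw$cache[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(cc$A, delta) + 2 * l2 * ly$W,
                         b = colSums(delta))
      delta <- tcrossprod(delta, ly$W)
      if (i > 1 && layers[[i - 1]]$type == "dense")
        delta <- delta * (fw$cache[[i - 1]]$Z > 0)
      # if previous layer is conv, ReLU mask is applied in the conv branch
    } else {
      Lout <- cc$L - ly$k + 1
      # delta arrives as n x (Lout*cout), position-fastest: same linear
      # layout as the (n*Lout) x cout pre-activation matrix
      dim(delta) <- c(n * Lout, ly$cout)
      dZ <- delta * (cc$Z > 0)
      grads[[i]] <- list(W = crossprod(cc$P, dZ) + 2 * l2 * ly$W,
                         b = colSums(dZ))
      dP <- tcrossprod(dZ, ly$W)
      idx <- convPatchIndex(cc$L, cc$C, ly$k)
      dA <- matrix(0, n, cc$L * cc$C)
      for (p in seq_len(Lout))
        dA[, idx[p, ]] <- dA[, idx[p, ], drop = FALSE] +
          dP[(p - 1L) * n + seq_len(n), , drop = FALSE]
      if (i > 1) {
        prev <- fw$cache[[i - 1]]
        mask <- prev$Z > 0
        dim(mask) <- c(n, cc$L * cc$C)
        delta <- dA * mask
      } else delta <- dA
    }
  }
  list(loss = loss, grads = grads, output = yhat)
}

# Flat-vector views of the layer parameters: Adam runs on one numeric
# vector, which avoids copying every weight matrix inside nested lists on
# each update.
flattenParams <- function(layers)
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)

# start/end offsets of each layer's W and b inside the flat vector
paramRanges <- function(layers) {
  off <- 0L
  lapply(layers, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    r <- list(w1 = off + 1L, w2 = off + nw,
              b1 = off + nw + 1L, b2 = off + nw + nb,
              dimW = dim(l$W))
    off <<- off + nw + nb
    r
  })
}

unflattenParams <- function(theta, skeleton, ranges = paramRanges(skeleton)) {
  out <- vector("list", length(skeleton))
  for (i in seq_along(skeleton)) {
    l <- skeleton[[i]]
    r <- ranges[[i]]
    W <- theta[r$w1:r$w2]
    dim(W) <- r$dimW
    l$W <- W
    l$b <- theta[r$b1:r$b2]
    out[[i]] <- l
  }
  out
}

# write a grads list into a preallocated flat vector
flattenGrads <- function(grads, ranges, g) {
  for (i in seq_along(grads)) {
    r <- ranges[[i]]
    g[r$w1:r$w2] <- grads[[i]]$W
    g[r$b1:r$b2] <- grads[[i]]$b
  }
  g
}

# 1 for weight entries, 0 for biases: L2 decay applies to weights only.
weightMask <- function(layers)
  unlist(lapply(layers, function(l)
    c(rep(1, length(l$W)), rep(0, length(l$b)))), use.names = FALSE)

# Stratified index split by concentration level; deterministic under seed.
stratifiedSplit <- function(conc, fraction, seed) {
  withLocalSeed(seed, {
    sel <- logical(length(conc))
    for (lv in unique(conc)) {
      idx <- which(conc == lv)
      nTake <- max(1L, round(fraction * length(idx)))
      sel[sample(idx, nTake)] <- TRUE
    }
    sel
  })
}

#' Training hyperparameters for the PCA-BP network
#'
#' @param featureMode "pca_scores" (default: top-`nComponents` window PCA
#'   scores fed as a length-`nComponents` sequence) or "raw" (window
#'   intensities fed directly).
#' @param nComponents PCA scores kept in pca_scores mode.
#' @param scoreTransform "asinh" (default) conditions the features before
#'   the network: each column is shifted by its training minimum, divided by
#'   the additive-noise scale (MAD of the last score column) and
#'   asinh-compressed, then rescaled to preserve the columns' original
#'   relative spread. This linearises the log-spaced concentration response
#'   along the leading score without changing its information content
#'   (asinh is monotone). "none" feeds the scores scaled by the leading
#'   column's sd.
#' @param learningRate Adam step size (full batch).
#' @param epochs full-batch epochs; the step size is halved every
#'   `lrHalveEvery` epochs.
#' @param lrHalveEvery epochs between halvings of the learning rate.
#' @param patience early-stopping patience on validation loss (0 = fixed
#'   schedule on all training data, the deterministic default).
#' @param valFraction fraction of training spectra held out for the
#'   early-stopping validation split (stratified by level; only used when
#'   `patience > 0`).
#' @param l2Lambda L2 weight decay.
#' @param margin sigmoid margin of the concentration scaler.
#' @param seed weight-initialisation / split seed.
#' @param architecture optional [NetworkArchitecture-class] override.
#' @return list of settings for [trainPcaBp()].
#' @export
pcaBpControl <- function(featureMode = c("pca_scores", "raw"),
                         nComponents = 16L,
                         scoreTransform = c("asinh", "none"),
                         learningRate = 2e-3,
                         epochs = 300L, lrHalveEvery = 100L,
                         patience = 0L, valFraction = 0.2,
                         l2Lambda = 1e-5, margin = 0.05, seed = 1L,
                         architecture = NULL) {
  list(featureMode = match.arg(featureMode), nComponents = nComponents,
       scoreTransform = match.arg(scoreTransform),
       learningRate = learningRate, epochs = epochs,
       lrHalveEvery = lrHalveEvery, patience = patience,
       valFraction = valFraction, l2Lambda = l2Lambda, margin = margin,
       seed = seed, architecture = architecture)
}

# fit the feature-conditioning state on a training feature matrix
fitFeatureState <- function(F, transform) {
  if (transform == "asinh") {
    shift <- apply(F, 2, min)
    # additive-noise scale from the (noise-dominated) last column, floored
    # at a small fraction of the signal spread so noise-free input stays
    # well conditioned
    s0 <- max(mad(F[, ncol(F)]), 1e-3 * sd(F[, 1]))
    if (!is.finite(s0) || s0 <= 0) s0 <- 1
    U <- asinh(sweep(F, 2, shift) / s0)
    sdF <- apply(F, 2, sd)
    sdU <- apply(U, 2, sd)
    sdU[!is.finite(sdU) | sdU == 0] <- 1
    ref <- if (sdF[1] > 0) sdF[1] else 1
    colScale <- (sdF / ref) / sdU
  } else {
    shift <- numeric(ncol(F))
    s0 <- 1
    ref <- if (sd(F[, 1]) > 0) sd(F[, 1]) else 1
    colScale <- rep(1 / ref, ncol(F))
  }
  list(shift = shift, s0 = s0, colScale = colScale)
}

applyFeatureState <- function(F, shift, s0, colScale, transform) {
  U <- sweep(F, 2, shift) / s0
  if (transform == "asinh") U <- asinh(U)
  sweep(U, 2, colScale, "*")
}

extractFeatures <- function(model, spectra) {
  F <- if (model@featureMode == "pca_scores") {
    projectRegionPCA(model@pca, spectra)
  } else {
    t(intensities(cropWindow(spectra, model@window)))
  }
  if (ncol(F) != length(model@featShift))
    stop("grid mismatch: model expects ", length(model@featShift),
         " feature columns, spectra give ", ncol(F))
  applyFeatureState(F, model@featShift, model@featS0, model@featColScale,
                    model@scoreTransform)
}

#' Train the PCA-BP concentration-regression network
#'
#' Fits the window PCA on the training spectra, scales the leading-score
#' axis to unit variance, maps concentrations onto (margin, 1 - margin) via
#' log10 scaling, and trains the convolutional network by full-batch Adam on
#' mean-squared error with L2 weight decay. A stratified validation split
#' drives early stopping; the best-validation weights are kept. Identical
#' data, control and seed give bitwise-identical weights.
#'
#' @param trainSpectra labelled [SpectraSet-class] with >= 2 concentration
#'   levels.
#' @param window input [SpectralWindow-class] (default 500-600 cm^-1).
#' @param control list from [pcaBpControl()].
#' @return a [PcaBpModel-class] carrying a per-epoch `trainingLog`.
#' @export
trainPcaBp <- function(trainSpectra, window = spectralWindow(500, 600),
                       control = pcaBpControl()) {
  conc <- concentrations(trainSpectra)
  if (anyNA(conc)) stop("all training spectra must have known concentrations")
  if (length(unique(conc)) < 2L)
    stop("training data has a single concentration level; target is degenerate")

  arch <- if (is.null(control$architecture)) {
    networkArchitecture(l2Lambda = control$l2Lambda)
  } else control$architecture

  if (control$featureMode == "pca_scores") {
    nc <- min(control$nComponents, ncol(trainSpectra) - 1L)
    pca <- fitRegionPCA(trainSpectra, window, nc)
    F <- pca@scores
  } else {
    pca <- NULL
    F <- t(intensities(cropWindow(trainSpectra, window)))
  }
  fs <- fitFeatureState(F, control$scoreTransform)
  X <- applyFeatureState(F, fs$shift, fs$s0, fs$colScale,
                         control$scoreTransform)

  scaler <- concentrationScaler(min(conc), max(conc), control$margin)
  target <- scaleConcentration(conc, scaler)

  useVal <- control$patience > 0 && control$valFraction > 0 &&
    min(table(conc)) >= 3
  if (useVal) {
    valIdx <- stratifiedSplit(conc, control$valFraction,
                              deriveSeed(control$seed, 7L, 7L))
    Xtr <- X[!valIdx, , drop = FALSE]; ttr <- target[!valIdx]
    Xva <- X[valIdx, , drop = FALSE]; tva <- target[valIdx]
  } else {
    Xtr <- X; ttr <- target; Xva <- NULL
  }

  skeleton <- initNetworkWeights(arch, ncol(X), control$seed)
  ranges <- paramRanges(skeleton)
  theta <- flattenParams(skeleton)
  mask <- weightMask(skeleton)
  gFlat <- numeric(length(theta))
  mAdam <- vAdam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  nEp <- control$epochs
  trainLoss <- valLoss <- rep(NA_real_, nEp)
  lastEp <- 0L
  for (ep in seq_len(nEp)) {
    lr <- control$learningRate * 0.5^((ep - 1) %/% control$lrHalveEvery)
    layers <- unflattenParams(theta, skeleton, ranges)
    lg <- nnLossGradient(layers, Xtr, ttr, l2 = 0)
    g <- flattenGrads(lg$grads, ranges, gFlat) +
      2 * arch@l2Lambda * theta * mask
    mAdam <- beta1 * mAdam + (1 - beta1) * g
    vAdam <- beta2 * vAdam + (1 - beta2) * g^2
    theta <- theta - lr * (mAdam / (1 - beta1^ep)) /
      (sqrt(vAdam / (1 - beta2^ep)) + epsAdam)
    trainLoss[ep] <- lg$loss + arch@l2Lambda * sum((theta * mask)^2)
    valLoss[ep] <- if (!is.null(Xva)) {
      pv <- nnForward(unflattenParams(theta, skeleton, ranges), Xva)$output
      mean((pv - tva)^2)
    } else mean((lg$output - ttr)^2)
    lastEp <- ep
    if (valLoss[ep] < best$loss - 1e-12)
      best <- list(loss = valLoss[ep], theta = theta, epoch = ep)
    if (control$patience > 0 && ep - best$epoch >= control$patience) break
  }
  # fixed-schedule runs keep the final weights; early-stopped runs restore
  # the best-validation snapshot
  finalTheta <- if (control$patience > 0) best$theta else theta
  log <- data.frame(epoch = seq_len(lastEp),
                    train_loss = trainLoss[seq_len(lastEp)],
                    val_loss = valLoss[seq_len(lastEp)])

  methods::new("PcaBpModel", architecture = arch,
               weights = unflattenParams(finalTheta, skeleton),
               featureMode = control$featureMode,
               scoreTransform = control$scoreTransform, pca = pca,
               featShift = fs$shift, featS0 = fs$s0,
               featColScale = fs$colScale,
               scaler = scaler, window = window, trainingLog = log)
}

#' Single forward pass through a trained network
#'
#' Deterministic given the stored weights; the sigmoid keeps the raw output
#' strictly inside (0, 1).
#'
#' @param model a [PcaBpModel-class].
#' @param input numeric vector (one feature vector, already on the network's
#'   input scale) or matrix of rows.
#' @return numeric vector of sigmoid outputs in (0, 1).
#' @export
forwardPass <- function(model, input) {
  X <- if (is.matrix(input)) input else matrix(input, nrow = 1)
  nnForward(model@weights, X)$output
}

#' @describeIn trainPcaBp predict concentrations (ppm) for new spectra.
#' @param object a fitted [PcaBpModel-class].
#' @param spectra a [SpectraSet-class] on a compatible grid.
#' @param ... unused.
#' @export
setMethod("predictConcentration", "PcaBpModel", function(object, spectra, ...) {
  X <- extractFeatures(object, spectra)
  unscaleConcentration(nnForward(object@weights, X)$output, object@scaler)
})

setMethod("show", "PcaBpModel", function(object) {
  sh <- networkShapes(object@architecture,
                      nrow(object@weights[[1]]$W) / object@weights[[1]]$cin)
  np <- sum(vapply(object@weights,
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat("PcaBpModel:", object@featureMode, "features in window",
      windowLabel(object@window), "cm-1\n")
  cat("  ", nrow(sh), "layers,", format(np, big.mark = ","),
      "parameters; trained", nrow(object@trainingLog), "epochs\n")
  cat(sprintf("  concentration range %g-%g ppm (log10 sigmoid scaling)\n",
              object@scaler@cMin, object@scaler@cMax))
})
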