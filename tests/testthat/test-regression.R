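test_that("concentration scaler is the stated log10 bijection", {
  sc <- concentrationScaler(0.01, 70, margin = 0.05)
  expect_equal(scaleConcentration(0.01, sc), 0.05)
  expect_equal(scaleConcentration(70, sc), 0.95)
  expect_equal(scaleConcentration(sqrt(0.01 * 70), sc), 0.5)

  set.seed(31)
  c0 <- exp(runif(100, log(0.01), log(70)))
  expect_equal(unscaleConcentration(scaleConcentration(c0, sc), sc), c0,
               tolerance = 1e-12)

  expect_error(scaleConcentration(0, sc), "> 0")
  expect_error(scaleConcentration(-3, sc), "> 0")
  expect_warning(scaleConcentration(100, sc), "clipped")
})

test_that("network shapes traverse the published architecture", {
  sh <- networkShapes(networkArchitecture(), 16)
  conv <- sh[sh$type == "conv1d", ]
  expect_equal(conv$out_channels, c(32, 64, 128, 256))
  expect_equal(conv$out_length, c(13, 10, 9, 9))
  expect_equal(sh$out_channels[sh$layer == "flatten"], 9 * 256)
  expect_equal(sh$out_channels[sh$type == "dense"], c(400, 200, 100, 50))
  expect_equal(tail(sh$out_channels, 1), 1)
  expect_error(networkShapes(networkArchitecture(), 3), "too short")
})

test_that("zero weights give sigmoid(0) = 0.5 and the mid-range concentration", {
  arch <- networkArchitecture(convStages = list(c(2, 2)), denseWidths = 4,
                              l2Lambda = 0)
  weights <- initNetworkWeights(arch, 6, seed = 1)
  weights <- lapply(weights, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  out <- sersquant:::nnForward(weights, matrix(rnorm(12), 2, 6))$output
  expect_equal(out, c(0.5, 0.5))
  sc <- concentrationScaler(0.01, 70)
  expect_equal(unscaleConcentration(0.5, sc), sqrt(0.01 * 70),
               tolerance = 1e-12)
})

test_that("backpropagated gradients match central finite differences", {
  arch <- networkArchitecture(convStages = list(c(3, 2), c(4, 2)),
                              denseWidths = c(5, 3), l2Lambda = 1e-3)
  set.seed(3)
  X <- matrix(rnorm(4 * 6), 4, 6)
  target <- runif(4, 0.1, 0.9)
  layers <- initNetworkWeights(arch, 6, seed = 9)
  # random biases keep pre-activations off the ReLU kink, where the
  # subgradient convention and a finite difference legitimately disagree
  set.seed(4)
  layers <- lapply(layers, function(l) {
    l$b <- rnorm(length(l$b), sd = 0.3); l
  })
  lg <- sersquant:::nnLossGradient(layers, X, target, arch@l2Lambda)
  eps <- 1e-6
  for (i in seq_along(layers)) for (nm in c("W", "b")) {
    th <- layers[[i]][[nm]]
    for (j in seq_along(th)) {
      up <- layers; up[[i]][[nm]][j] <- th[j] + eps
      dn <- layers; dn[[i]][[nm]][j] <- th[j] - eps
      fd <- (sersquant:::nnLossGradient(up, X, target, arch@l2Lambda)$loss -
             sersquant:::nnLossGradient(dn, X, target, arch@l2Lambda)$loss) /
        (2 * eps)
      g <- as.numeric(lg$grads[[i]][[nm]])[j]
      expect_equal(g, fd, tolerance = 1e-4)
    }
  }
})

test_that("training recovers a noiseless concentration series", {
  ds <- generateDataset(singleBandLibrary(), quietResponse(),
                        acquisitionGrid(), levels = c(0.1, 0.5, 2, 10, 50),
                        replicates = 4, seed = 2)
  model <- trainPcaBp(ds, w500(),
                      pcaBpControl(nComponents = 8, epochs = 200,
                                   lrHalveEvery = 80, seed = 5))
  rep <- evaluateModel(model, ds)
  expect_gte(rep@rSquaredLog, 0.999)
})

test_that("extreme L2 shrinks the network to a constant mid-range output", {
  ds <- generateDataset(replicates = 3, seed = 4)
  model <- trainPcaBp(ds, w500(),
                      pcaBpControl(nComponents = 8, epochs = 30,
                                   l2Lambda = 100, seed = 1))
  pred <- predictConcentration(model, ds)
  expect_lt(sd(log10(pred)), 0.05)
  expect_equal(median(pred), sqrt(0.01 * 70), tolerance = 0.5)
})

test_that("degenerate training inputs are rejected", {
  ds <- generateDataset(levels = 5, replicates = 6, seed = 1)
  expect_error(trainPcaBp(ds, w500(), pcaBpControl(epochs = 5)),
               "single concentration level")
  expect_error(fitPlsr(ds, w500(), 2), "single concentration level")
})

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- generateDataset(replicates = 2, seed = 10)
  ctrl <- pcaBpControl(nComponents = 8, epochs = 15, seed = 77)
  m1 <- trainPcaBp(ds, w500(), ctrl)
  m2 <- trainPcaBp(ds, w500(), ctrl)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@trainingLog, m2@trainingLog)
  r1 <- evaluateModel(m1, ds); r2 <- evaluateModel(m2, ds)
  expect_identical(r1@yPred, r2@yPred)
})

test_that("PLSR is exact on a one-direction linear problem", {
  x <- seq(500, 600, 2)
  profile <- exp(-(x - 586)^2 / 150)
  conc <- rep(c(0.1, 0.5, 2, 10, 50), each = 3)
  sc <- concentrationScaler(min(conc), max(conc))
  spectra <- spectraFromMatrix(outer(profile, scaleConcentration(conc, sc)),
                               x, conc)
  model <- fitPlsr(spectra, w500(), 1)
  rep <- evaluateModel(model, spectra)
  expect_equal(rep@rSquaredLog, 1, tolerance = 1e-9)
  expect_equal(rep@yPred, conc, tolerance = 1e-6)
})

test_that("PLSR coefficients match an iterative NIPALS oracle", {
  set.seed(19)
  n <- 8; p <- 6; A <- 3
  X <- matrix(rnorm(n * p), n, p)
  conc <- exp(runif(n, log(0.1), log(10)))
  spectra <- spectraFromMatrix(t(X), seq(500, by = 2, length.out = p), conc)
  model <- fitPlsr(spectra, spectralWindow(500, 500 + 2 * (p - 1)), A)

  # independent oracle: classical NIPALS PLS1 with explicit iteration
  sc <- model@scaler
  y <- scaleConcentration(conc, sc)
  E <- scale(X, scale = FALSE); f <- y - mean(y)
  W <- P <- matrix(0, p, A); q <- numeric(A)
  for (a in 1:A) {
    w <- rep(1 / sqrt(p), p)
    for (it in 1:500) {
      tvec <- E %*% w
      wNew <- crossprod(E, f)        # single-response NIPALS weight update
      wNew <- wNew / sqrt(sum(wNew^2))
      if (sum(abs(wNew - w)) < 1e-14) { w <- wNew; break }
      w <- wNew
    }
    tvec <- E %*% w
    pvec <- crossprod(E, tvec) / sum(tvec^2)
    qa <- sum(f * tvec) / sum(tvec^2)
    E <- E - tvec %*% t(pvec)
    f <- f - qa * tvec
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  expect_equal(model@coefficients, as.numeric(beta), tolerance = 1e-6)
})

test_that("regression reports compute the stated identities", {
  perfect <- regressionReport(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect@rSquared, 1)
  expect_equal(perfect@rmse, 0)
  expect_equal(perfect@fitLineSlope, 1, tolerance = 1e-12)
  expect_equal(perfect@fitLineIntercept, 0, tolerance = 1e-12)

  null <- regressionReport(c(1, 2, 3), rep(2, 3))
  expect_equal(null@rSquared, 0)

  hand <- regressionReport(c(1, 2, 3), c(1, 2, 4))
  expect_equal(hand@rSquared, 0.5)   # 1 - 1/2

  expect_error(regressionReport(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(regressionReport(numeric(0), numeric(0)), "empty")
})
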