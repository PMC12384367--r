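test_that("rank-1 data put all variance on the first component", {
  x <- seq(500, 600, 2)
  profile <- exp(-(x - 550)^2 / 200)
  coefs <- c(1, 3, -2, 5, 0.5, 9)
  spectra <- spectraFromMatrix(outer(profile, coefs), x)
  pca <- fitRegionPCA(spectra, w500(), 3)
  expect_equal(varianceContribution(pca), 1, tolerance = 1e-12)
  expect_equal(explainedFraction(pca)[2:3], c(0, 0), tolerance = 1e-12)
  expect_equal(sum(explainedFraction(pca)), 1, tolerance = 1e-9)
  # asking beyond min(n - 1, p) truncates with a warning
  expect_warning(fitRegionPCA(spectra, w500(), 12), "truncating")
})

test_that("explained fractions match an eigendecomposition oracle", {
  set.seed(10)
  wn <- seq(1, 20)
  X <- matrix(rnorm(10 * 20), 10, 20)              # 10 samples x 20 points
  spectra <- spectraFromMatrix(t(X), wn)
  pca <- fitRegionPCA(spectra, spectralWindow(1, 20), 9)

  ev <- eigen(cov(X), symmetric = TRUE)$values     # independent oracle
  expect_equal(explainedFraction(pca),
               (ev / sum(ev))[1:9], tolerance = 1e-10)

  # scores reproduce (X - mean) t(loadings); loading rows orthonormal
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(pcaScores(pca), Xc %*% t(pcaLoadings(pca)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(tcrossprod(pcaLoadings(pca)), diag(9),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("full-rank reconstruction recovers the data", {
  set.seed(2)
  wn <- seq(1, 12)
  X <- matrix(rnorm(8 * 12), 8, 12)
  pca <- fitRegionPCA(spectraFromMatrix(t(X), wn), spectralWindow(1, 12), 7)
  rec <- sweep(pcaScores(pca) %*% pcaLoadings(pca), 2, pca@meanVector, "+")
  expect_equal(rec, X, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("sign convention makes the decomposition deterministic", {
  ds <- generateDataset(replicates = 3, seed = 6)
  p1 <- fitRegionPCA(ds, w500(), 5)
  p2 <- fitRegionPCA(ds, w500(), 5)
  expect_identical(pcaLoadings(p1), pcaLoadings(p2))
  for (k in 1:5) {
    load <- pcaLoadings(p1)[k, ]
    expect_gt(load[which.max(abs(load))], 0)
  }
})

test_that("variance contribution is invariant to global rescaling", {
  ds <- generateDataset(replicates = 4, seed = 8)
  p1 <- fitRegionPCA(ds, w500(), 4)
  scaled <- spectraFromMatrix(intensities(ds) * 37.5, wavenumbers(ds),
                              concentrations(ds))
  p2 <- fitRegionPCA(scaled, w500(), 4)
  expect_equal(varianceContribution(p1), varianceContribution(p2),
               tolerance = 1e-12)
})

test_that("selectRegion picks the pyrene window and breaks ties low", {
  ds <- generateDataset(replicates = 8, seed = 12)
  sel <- selectRegion(ds)
  expect_equal(c(sel$window@low, sel$window@high), c(500, 600))
  expect_length(sel$regions, 4)
  expect_named(sel$contributions,
               c("350-405", "410-490", "500-600", "1190-1250"))

  # single window: returned as-is
  one <- selectRegion(ds, list(w500()))
  expect_equal(c(one$window@low, one$window@high), c(500, 600))

  # two windows with identical data: deterministic lower-bound tie-break
  twin <- analyteLibrary("twin", list(peakSpec(550, 1, 20),
                                      peakSpec(750, 1, 20)))
  tds <- generateDataset(twin, responseModel(noiseSd = 0),
                         acquisitionGrid(), replicates = 4, seed = 3)
  tie <- suppressWarnings(selectRegion(tds, list(spectralWindow(700, 800),
                                                 spectralWindow(500, 600))))
  expect_equal(tie$window@low, 500)
})
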