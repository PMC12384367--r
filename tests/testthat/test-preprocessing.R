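test_that("cropWindow keeps both endpoints and counts points correctly", {
  ds <- generateDataset(replicates = 1, seed = 1)

  expect_equal(nrow(cropWindow(ds, w500())), 51)        # 500,502,...,600
  expect_equal(nrow(cropWindow(ds, spectralWindow(350, 405))), 28)  # ...,404
  full <- cropWindow(ds, spectralWindow(200, 1800))
  expect_identical(intensities(full), intensities(ds))
  expect_error(cropWindow(ds, spectralWindow(4000, 4100)), "no overlap")
})

test_that("Gaussian fit recovers noiseless parameters to machine precision", {
  x <- seq(200, 1800, 2)
  cases <- list(c(center = 586, height = 100, fwhm = 20, offset = 7),
                c(center = 545.3, height = 2500, fwhm = 11.7, offset = -40),
                c(center = 590, height = 3, fwhm = 35, offset = 0))
  for (p in cases) {
    sigma <- p["fwhm"] / (2 * sqrt(2 * log(2)))
    y <- p["height"] * exp(-(x - p["center"])^2 / (2 * sigma^2)) + p["offset"]
    fit <- fitGaussianPeak(spectraFromMatrix(matrix(y, ncol = 1), x), w500())
    expect_true(fit@converged)
    expect_equal(fit@center, unname(p["center"]), tolerance = 1e-6)
    expect_equal(fit@height, unname(p["height"]), tolerance = 1e-6)
    expect_equal(fit@fwhm, unname(p["fwhm"]), tolerance = 1e-6)
    expect_equal(fit@offset, unname(p["offset"]), tolerance = 1e-4)
    # area identity holds for every returned fit
    expect_equal(fit@area, fit@height * fit@fwhm * sqrt(pi / (4 * log(2))),
                 tolerance = 1e-12)
  }
})

test_that("noisy fit agrees with a brute-force grid-search oracle", {
  x <- seq(500, 600, 2)
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  set.seed(42)
  y <- 100 * exp(-(x - 586)^2 / (2 * sigma^2)) + rnorm(length(x), 0, 2)

  # oracle: exhaustive search over (center, height, FWHM) at 0.1 granularity
  centers <- seq(583, 589, 0.1)
  fwhms <- seq(17, 23, 0.1)
  heights <- seq(90, 110, 0.1)
  best <- c(NA, NA, NA); bestSse <- Inf
  for (ct in centers) for (fw in fwhms) {
    g <- exp(-(x - ct)^2 / (2 * (fw / (2 * sqrt(2 * log(2))))^2))
    sse <- vapply(heights, function(h) sum((h * g - y)^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < bestSse) { bestSse <- sse[i]; best <- c(ct, heights[i], fw) }
  }

  fit <- fitGaussianPeak(spectraFromMatrix(matrix(y, ncol = 1), x), w500())
  # continuous optimum within one oracle grid cell of the discrete optimum
  expect_equal(fit@center, best[1], tolerance = 0.1)
  expect_equal(fit@height, best[2], tolerance = 0.2)
  expect_equal(fit@fwhm, best[3], tolerance = 0.2)
  expect_lte(sum((fit@height *
                    exp(-(x - fit@center)^2 / (2 * (fit@fwhm /
                      (2 * sqrt(2 * log(2))))^2)) + fit@offset - y)^2),
             bestSse)
})

test_that("fit is invariant to adding a constant and flags degenerate input", {
  sp <- generateSpectrum(pyreneLibrary(),
                         responseModel(replicateCv = 0, noiseSd = 2),
                         acquisitionGrid(), 10, seed = 9)
  f1 <- fitGaussianPeak(sp, w500())
  shifted <- spectraFromMatrix(intensities(sp) + 1000, wavenumbers(sp))
  f2 <- fitGaussianPeak(shifted, w500())
  expect_equal(f1@center, f2@center, tolerance = 1e-6)
  expect_equal(f1@height, f2@height, tolerance = 1e-6)
  expect_equal(f1@fwhm, f2@fwhm, tolerance = 1e-6)
  expect_equal(f2@offset - f1@offset, 1000, tolerance = 1e-4)

  flat <- spectraFromMatrix(matrix(5, 801, 1), seq(200, 1800, 2))
  expect_error(fitGaussianPeak(flat, w500()), "flat window")
  tiny <- spectraFromMatrix(matrix(1:3, ncol = 1), c(500, 550, 600))
  expect_error(fitGaussianPeak(tiny, w500()), "fewer than 5")
})

test_that("the pyrene band is located at 586 cm-1", {
  sp <- generateSpectrum(pyreneLibrary(), responseModel(), acquisitionGrid(),
                         10, seed = 21)
  fit <- fitGaussianPeak(sp, w500())
  expect_equal(fit@center, 586, tolerance = 1)
})

test_that("blank-noise estimation follows the sample-sd convention", {
  x <- seq(500, 600, 2)
  set.seed(7)
  base <- rnorm(length(x))
  identical3 <- spectraFromMatrix(cbind(base, base, base), x)
  expect_equal(estimateBlankNoise(identical3, w500()), 0)
  expect_equal(estimateBlankNoise(identical3, w500(), statistic = "max"), 0)

  # closed form: max statistics (0, 0, h) have sample sd h / sqrt(3)
  m <- matrix(0, length(x), 3); m[26, 3] <- 9
  expect_equal(estimateBlankNoise(spectraFromMatrix(m, x), w500(),
                                  statistic = "max"),
               9 / sqrt(3))

  expect_error(estimateBlankNoise(identical3[, 1:2], w500()), "at least 3")
})

test_that("blank-noise estimate matches a Monte-Carlo rerun", {
  x <- seq(500, 600, 2)
  gen <- function(seed) {
    set.seed(seed)
    spectraFromMatrix(matrix(rnorm(51 * 200, 0, 3), 51, 200), x)
  }
  # fixed-profile matched-filter statistic: sd has the closed form
  # sigma / sqrt(sum((g - mean(g))^2)) under additive N(0, sigma^2) noise
  sigmaG <- 20 / (2 * sqrt(2 * log(2)))
  g <- exp(-(x - 586)^2 / (2 * sigmaG^2))
  expected <- 3 / sqrt(sum((g - mean(g))^2))
  est1 <- estimateBlankNoise(gen(1), w500(), center = 586, fwhm = 20)
  est2 <- estimateBlankNoise(gen(2), w500(), center = 586, fwhm = 20)
  expect_equal(est1, expected, tolerance = 0.15)
  expect_equal(est2, expected, tolerance = 0.15)
  expect_equal(est1, est2, tolerance = 0.2)
})
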