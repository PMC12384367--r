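test_that("generator honours the closed-form Langmuir response", {
  grid <- acquisitionGrid()
  lib <- singleBandLibrary()

  # zero input: no analyte, no noise, no baseline
  sp0 <- generateSpectrum(lib, quietResponse(), grid, 0, seed = 1)
  expect_true(all(intensities(sp0) == 0))

  # saturation limit: height -> relAmplitude * iMax as c -> Inf
  spSat <- generateSpectrum(lib, quietResponse(), grid, 1e9, seed = 1)
  expect_equal(max(intensities(spSat)), 3000, tolerance = 1e-6)

  # half-saturation identity at c = 1/kAds
  spHalf <- generateSpectrum(lib, quietResponse(), grid, 1 / 0.05, seed = 1)
  expect_equal(max(intensities(spHalf)), 1500, tolerance = 1e-9)

  # rejected inputs
  expect_error(generateSpectrum(lib, quietResponse(), grid, -1), ">= 0")
  badLib <- analyteLibrary("x", list(peakSpec(50)))
  expect_error(generateSpectrum(badLib, quietResponse(), grid, 1),
               "outside the acquisition grid")
})

test_that("datasets have the stated layout and are seed-deterministic", {
  ds <- generateDataset(replicates = 20, seed = 3)
  expect_equal(ncol(ds), 9 * 20)
  expect_equal(sort(unique(concentrations(ds))), defaultLevels())
  expect_equal(as.vector(table(concentrations(ds))), rep(20, 9))

  ds2 <- generateDataset(replicates = 20, seed = 3)
  expect_identical(intensities(ds), intensities(ds2))
  ds3 <- generateDataset(replicates = 20, seed = 4)
  expect_false(identical(intensities(ds), intensities(ds3)))

  # generateSpectrum and generateDataset agree spectrum by spectrum
  s <- sersquant:::deriveSeed(3, 1, 1)
  sp <- generateSpectrum(pyreneLibrary(), responseModel(), acquisitionGrid(),
                         defaultLevels()[1], seed = s)
  expect_equal(intensities(ds)[, 1], intensities(sp)[, 1])
})

test_that("replicate scatter matches the configured 9.6% RSD", {
  # peak heights at a fixed level are A(c) * eps, so their RSD estimates the
  # configured lognormal CV; n = 200 keeps the Monte-Carlo error ~0.5%
  ds <- generateDataset(singleBandLibrary(),
                        responseModel(replicateCv = 0.096, noiseSd = 0,
                                      baselineCoeffs = 0),
                        acquisitionGrid(), levels = 10, replicates = 200,
                        seed = 11)
  heights <- apply(intensities(cropWindow(ds, w500())), 2, max)
  expect_equal(rsd(heights), 9.6, tolerance = 0.15)
})

test_that("mean response is strictly increasing and concave in concentration", {
  levels <- defaultLevels()
  ds <- generateDataset(singleBandLibrary(), quietResponse(),
                        acquisitionGrid(), levels = levels, replicates = 1,
                        seed = 1)
  h <- apply(intensities(cropWindow(ds, w500())), 2, max)
  expect_true(all(diff(h) > 0))
  slopes <- diff(h) / diff(levels)        # divided differences on the
  expect_true(all(diff(slopes) < 0))      # log-spaced grid: concavity
})

test_that("spectra round-trip exactly through the CSV writer/reader", {
  ds <- generateDataset(replicates = 1, seed = 5)
  sp <- ds[, 4]
  path <- tempfile(fileext = ".csv")
  writeSpectrumCsv(sp, path)
  back <- readSpectrumCsv(path, concentration = concentrations(sp))
  expect_identical(intensities(back)[, 1], intensities(sp)[, 1])
  expect_identical(wavenumbers(back), wavenumbers(sp))

  dir <- tempfile()
  manifest <- writeSpectraSet(ds[, 1:6], dir)
  expect_equal(nrow(manifest), 6)
  rt <- readSpectraSet(file.path(dir, "manifest.csv"))
  expect_identical(unname(intensities(rt)), unname(intensities(ds[, 1:6])))
  expect_equal(concentrations(rt), concentrations(ds[, 1:6]))
})
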