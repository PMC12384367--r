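# Shared fixtures: everything is generated in code at test time.

# deterministic single-band world with all noise sources off
quietResponse <- function(iMax = 3000, kAds = 0.05)
  responseModel(iMax = iMax, kAds = kAds, replicateCv = 0,
                noiseSd = 0, baselineCoeffs = 0)

singleBandLibrary <- function(center = 586, fwhm = 20)
  analyteLibrary("pyrene-586", list(peakSpec(center, 1, fwhm)))

w500 <- function() spectralWindow(500, 600)

# small SpectraSet straight from a matrix
spectraFromMatrix <- function(mat, wn, conc = rep(NA_real_, ncol(mat)))
  SpectraSet(mat, wn, concentration = conc)

# one full default train/test evaluation for a master seed; epochs
# configurable so the many-seed comparison block can run a reduced budget
runSeedEval <- function(seedD, epochs = 300L, plsr = TRUE) {
  ds <- generateDataset(seed = seedD)
  conc <- concentrations(ds)
  trainIdx <- sersquant:::stratifiedSplit(conc, 0.7,
                                          sersquant:::deriveSeed(seedD, 11L, 3L))
  train <- ds[, trainIdx]
  test <- ds[, !trainIdx]
  ctrl <- pcaBpControl(seed = sersquant:::deriveSeed(seedD, 13L, 1L),
                       epochs = epochs,
                       lrHalveEvery = max(20L, epochs %/% 3L))
  model <- trainPcaBp(train, w500(), ctrl)
  out <- list(pcabp = evaluateModel(model, test))
  if (plsr) out$plsr <- evaluateModel(fitPlsr(train, w500(), 10L), test)
  out
}
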