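test_that("linear calibration reproduces closed-form least squares", {
  cal <- fitCalibration(c(1, 2, 3), 5 * c(1, 2, 3) + 2, transform = "linear")
  expect_equal(cal@slope, 5)
  expect_equal(cal@intercept, 2)
  expect_equal(rSquared(cal), 1)

  # hand case c = (0, 1, 2), I = (0, 1, 4): slope 2, intercept -1/3;
  # SS_res = 2/3, SS_tot = 26/3 so R^2 = 12/13 (checked against lm below)
  cal2 <- fitCalibration(c(0, 1, 2), c(0, 1, 4), transform = "linear")
  expect_equal(cal2@slope, 2)
  expect_equal(cal2@intercept, -1 / 3)
  expect_equal(rSquared(cal2), 12 / 13)
  fit <- lm(y ~ x, data.frame(x = c(0, 1, 2), y = c(0, 1, 4)))
  expect_equal(rSquared(cal2), summary(fit)$r.squared, tolerance = 1e-12)

  expect_error(fitCalibration(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fitCalibration(c(1, 2, 3), c(4, 4, 4)), "undefined")
  expect_error(fitCalibration(c(0, 1, 2), c(0, 1, 4)), "> 0")  # log10 axis
})

test_that("calibration matches a normal-equations oracle on random inputs", {
  set.seed(23)
  for (i in 1:10) {
    x <- sort(runif(6, 0.1, 50))
    y <- runif(6, -5, 100)
    cal <- fitCalibration(x, y, transform = "linear")
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(cal@intercept, beta[1], tolerance = 1e-10)
    expect_equal(cal@slope, beta[2], tolerance = 1e-10)
  }
})

test_that("LOD follows the SNR = 3 definition and its scaling laws", {
  cal <- fitCalibration(c(1, 2, 3), c(3, 6, 9), transform = "linear")
  expect_equal(lod(computeLod(cal, 1)), 1)              # 3 * 1 / 3 ppm
  expect_warning(zero <- computeLod(cal, 0), "zero")
  expect_equal(lod(zero), 0)

  # homogeneity: LOD doubles with the noise, halves with the slope
  expect_equal(lod(computeLod(cal, 2)), 2 * lod(computeLod(cal, 1)))
  cal2 <- fitCalibration(c(1, 2, 3), c(6, 12, 18), transform = "linear")
  expect_equal(lod(computeLod(cal2, 1)), lod(computeLod(cal, 1)) / 2)

  down <- fitCalibration(c(1, 2, 3), c(9, 6, 3), transform = "linear")
  expect_error(computeLod(down, 1), "slope")
})

test_that("rsd is the percent sample CV and scale-invariant", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(9, 10, 11)), 10)   # sd 1, mean 10
  v <- c(3, 7, 9, 13)
  expect_equal(rsd(17.3 * v), rsd(v), tolerance = 1e-12)
  expect_error(rsd(5), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero-mean")
})

test_that("per-level calibration table summarises fitted band heights", {
  ds <- generateDataset(levels = c(1, 10, 50), replicates = 3, seed = 15)
  tab <- calibrationTable(ds)
  expect_equal(tab$concentration_ppm, c(1, 10, 50))
  expect_equal(tab$n, rep(3, 3))
  expect_true(all(diff(tab$mean_height) > 0))
  amp <- 3000 * 0.05 * c(1, 10, 50) / (1 + 0.05 * c(1, 10, 50))
  expect_equal(tab$mean_height, amp, tolerance = 0.12)
})
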