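test_that("OD420 standard curve: fit, inversion and guard rails", {
  od <- c(0.1, 0.2, 0.4, 0.8)
  curve <- fitODCurve(od, 1e9 * od)
  expect_equal(curve@slope, 1e9)
  expect_equal(curve@intercept, 0, tolerance = 1e-6)
  expect_equal(curve@r2, 1)

  expect_equal(cfuFromOD(curve, 0.3), 3e8, tolerance = 1e-6)
  expect_equal(odFromCFU(curve, cfuFromOD(curve, 0.25)), 0.25,
               tolerance = 1e-9)
  expect_warning(cfuFromOD(curve, 2), "extrapolat")

  # recovery from noisy calibration points
  set.seed(53)
  odn <- seq(0.05, 1, length.out = 12)
  cfun <- 2e9 * odn + 1e7 + rnorm(12, 0, 0.02 * 2e9 * 0.95)
  noisy <- fitODCurve(odn, cfun)
  expect_lt(abs(noisy@slope - 2e9) / 2e9, 0.05)

  expect_error(fitODCurve(c(0.1, 0.2), c(1, 2)), "3 calibration")
  expect_error(fitODCurve(rep(0.2, 4), 1:4), "variance")
})

test_that("serial-dilution CFU arithmetic", {
  expect_equal(cfuFromDilution(37, 1e6, 0.1), 3.7e8)
  expect_equal(cfuFromDilution(0, 1e4, 0.1), 0)
  expect_equal(cfuFromDilution(50, 1, 1), 50)
  expect_error(cfuFromDilution(10, 1e3, 0), "positive")
})

test_that("bound MB mass follows mass = concentration x volume", {
  # 1 uL of 1% w/v MB is 10 ug
  expect_equal(mbMass(1, 1), 1e-5)

  # residuals equal to input leave nothing bound
  led <- LabelLedger(1, 1.3, washConcPct = c(0.8, 0.2),
                     washVolumeUl = c(1.3, 1.3))
  expect_equal(mbBoundMass(led), 0, tolerance = 1e-20)

  # 13 ug in, 12.999999 ug recovered: 1 pg bound
  led2 <- LabelLedger(1, 1.3, washConcPct = 12.999999e-6 / 1e-5,
                      washVolumeUl = 1)
  expect_equal(mbBoundMass(led2), 1e-12, tolerance = 1e-6)

  # splitting one wash into two with the same total mass changes nothing
  one <- LabelLedger(1, 2, washConcPct = 0.5, washVolumeUl = 2)
  two <- LabelLedger(1, 2, washConcPct = c(0.5, 0.5),
                     washVolumeUl = c(1.5, 0.5))
  expect_equal(mbBoundMass(one), mbBoundMass(two))

  over <- LabelLedger(1, 1, washConcPct = 2, washVolumeUl = 1)
  expect_error(mbBoundMass(over), "inconsistent")
})

test_that("order-of-magnitude comparisons reproduce the published
           contrasts", {
  # inhibitory MB concentration vs MBEC supernatant concentration
  expect_identical(ordersOfMagnitude(1e-3, 1e-5), 2L)
  # clinical intravenous dose (1 mg/kg x 70 kg = 70 mg) vs picogram label
  expect_identical(ordersOfMagnitude(70e-3, 1e-12), 11L)
  expect_identical(ordersOfMagnitude(3.2, 3.2), 0L)
  expect_identical(ordersOfMagnitude(5, 2e3), -ordersOfMagnitude(2e3, 5))
  expect_error(ordersOfMagnitude(0, 1), "positive")
})

test_that("MOI is bacteria per cell", {
  expect_equal(computeMOI(5e8, 5e6), 100)
  expect_equal(computeMOI(0, 1e6), 0)
  expect_equal(computeMOI(2e6, 1e5), 20)
  expect_error(computeMOI(10, 0), "positive")
})
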