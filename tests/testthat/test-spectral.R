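test_that("sum-normalization rescales to unit total and preserves shape", {
  s <- EmissionSpectrum(c(650, 660, 670, 680), c(1, 3, 4, 2))
  expect_equal(intensity(normalizeSpectrum(s)), c(0.1, 0.3, 0.4, 0.2))

  # idempotence and scale invariance
  n1 <- normalizeSpectrum(s)
  expect_equal(intensity(normalizeSpectrum(n1)), intensity(n1))
  red <- reducedBasis(defaultSpectralModel())
  half <- EmissionSpectrum(wavelength(red), 0.5 * intensity(red))
  expect_equal(intensity(normalizeSpectrum(half)), intensity(red))

  expect_error(normalizeSpectrum(EmissionSpectrum(1:3, c(0, 0, 0))),
               "degenerate")

  # property: unit total and unchanged peak for random spectra
  set.seed(71)
  for (i in 1:20) {
    r <- randomSpectrum()
    n <- normalizeSpectrum(r)
    expect_equal(sum(intensity(n)), 1, tolerance = 1e-9)
    expect_identical(findPeak(n), findPeak(r))
  }
})

test_that("peak finder hits the published emission and absorbance maxima", {
  m <- defaultSpectralModel()
  expect_equal(findPeak(reducedBasis(m)), 696)
  expect_equal(findPeak(oxidizedBasis(m)), 760)
  expect_equal(findPeak(reducedBasis(defaultAbsorbanceModel())), 665)

  spike <- EmissionSpectrum(c(650, 700, 750), c(0, 5, 0))
  expect_equal(findPeak(spike), 700)
  expect_warning(p <- findPeak(EmissionSpectrum(1:4, rep(2, 4))), "flat")
  expect_equal(p, 1)
})

test_that("band integration is a gained trapezoid: width, linearity,
           additivity", {
  flat <- EmissionSpectrum(650:810, rep(1, 161))
  af647 <- BandPassChannel("AF647", 655, 685)
  expect_equal(bandIntegral(flat, af647), 30)
  expect_equal(bandIntegral(flat, BandPassChannel("AF647", 655, 685,
                                                  gain = 2)), 60)

  set.seed(5)
  s <- randomSpectrum(80)
  ch <- BandPassChannel("w", 650, 820)
  s2 <- EmissionSpectrum(wavelength(s), 2.5 * intensity(s))
  expect_equal(bandIntegral(s2, ch), 2.5 * bandIntegral(s, ch))
  lohalf <- BandPassChannel("a", 650, 700)
  hihalf <- BandPassChannel("b", 700, 820)
  expect_equal(bandIntegral(s, lohalf) + bandIntegral(s, hihalf),
               bandIntegral(s, ch))

  expect_warning(z <- bandIntegral(flat, BandPassChannel("uv", 300, 400)),
                 "overlap")
  expect_equal(z, 0)

  # the construction that makes the red shift monotone: the oxidized
  # basis is relatively far-red-heavy
  m <- defaultSpectralModel()
  apc <- modelChannels(m)$APCCy7
  a <- modelChannels(m)$AF647
  expect_gt(bandIntegral(oxidizedBasis(m), apc) /
              bandIntegral(oxidizedBasis(m), a),
            bandIntegral(reducedBasis(m), apc) /
              bandIntegral(reducedBasis(m), a))
})

test_that("predicted red-shift ratio interpolates its basis endpoints and
           is strictly monotone in the oxidized fraction", {
  m <- defaultSpectralModel()
  apc <- modelChannels(m)$APCCy7
  a647 <- modelChannels(m)$AF647
  r0 <- bandIntegral(reducedBasis(m), apc) /
    bandIntegral(reducedBasis(m), a647)
  r1 <- bandIntegral(oxidizedBasis(m), apc) /
    bandIntegral(oxidizedBasis(m), a647)
  expect_equal(predictRedshiftRatio(m, 0), r0)
  expect_equal(predictRedshiftRatio(m, 1), r1)
  mid <- predictRedshiftRatio(m, 0.5)
  expect_gt(mid, r0)
  expect_lt(mid, r1)

  grid <- predictRedshiftRatio(m, seq(0, 1, length.out = 101))
  expect_true(all(diff(grid) > 0))

  # degenerate model: AF647 window off the grid
  bad <- m
  bad@channels$AF647 <- BandPassChannel("AF647", 300, 400)
  expect_error(suppressWarnings(predictRedshiftRatio(bad, 0.5)),
               "degenerate")
})

test_that("unmixing recovers the oxidized fraction", {
  m <- defaultSpectralModel()
  # noise-free round trip at the grid of canonical fractions
  for (rho in c(0, 0.25, 0.5, 0.75, 1)) {
    u <- unmixOxidizedFraction(mixSpectra(m, rho), m)
    expect_equal(u$rho, rho, tolerance = 1e-6)
    expect_lt(u$residual, 1e-9)
  }
  # scale invariance: unmixing works on unnormalized input
  obs <- mixSpectra(m, 0.3)
  scaled <- EmissionSpectrum(wavelength(obs), 1234 * intensity(obs))
  expect_equal(unmixOxidizedFraction(scaled, m)$rho, 0.3,
               tolerance = 1e-6)

  # off-grid observation is resampled
  w2 <- seq(650, 820, by = 2)
  y2 <- approx(wavelength(obs), intensity(obs), w2)$y
  expect_equal(unmixOxidizedFraction(EmissionSpectrum(w2, y2), m)$rho,
               0.3, tolerance = 0.01)

  # Monte-Carlo recovery under 5% multiplicative noise
  set.seed(19)
  truth <- 0.4
  grid <- wavelength(reducedBasis(m))
  base <- intensity(mixSpectra(m, truth))
  est <- replicate(200, {
    noisy <- base * rlnorm(length(base), 0, 0.05)
    unmixOxidizedFraction(EmissionSpectrum(grid, noisy), m)$rho
  })
  expect_lt(abs(mean(est) - truth), 0.05)

  # identical bases are unidentifiable
  degen <- m
  degen@oxidized <- m@reduced
  expect_error(unmixOxidizedFraction(mixSpectra(m, 0.5), degen),
               "unidentifiable")
})

test_that("peroxide drives a monotone red shift of the absorbance model", {
  conc <- c(0, 0.5, 1, 2, 5, 10)
  rho <- peroxideOxidizedFraction(conc)
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0 & rho < 1))

  am <- defaultAbsorbanceModel()
  far <- modelChannels(am)$far
  near <- modelChannels(am)$near
  ratios <- vapply(rho, function(r) {
    mx <- mixSpectra(am, r)
    bandIntegral(mx, far) / bandIntegral(mx, near)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})
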