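map <- defaultChannelMap()

test_that("the merged virtual MB channel is the per-event linear sum", {
  et <- EventTable(cbind(AF647 = c(100, 0), AF700 = c(50, 0),
                         APCCy7 = c(25, 0)))
  merged <- mergeMBChannel(et, map)
  expect_equal(unname(exprs(merged)[, "MBmerged"]), c(175, 0))

  # merged dominates each component per event and in geometric MFI
  set.seed(13)
  for (i in 1:5) {
    ex <- matrix(rlnorm(300, 3, 1), ncol = 3,
                 dimnames = list(NULL, map@sources))
    m2 <- mergeMBChannel(EventTable(ex), map)
    v <- exprs(m2)
    expect_true(all(v[, "MBmerged"] >= v[, map@sources]))
    for (ch in map@sources)
      expect_gte(geometricMFI(v[, "MBmerged"]), geometricMFI(v[, ch]))
  }

  # negative intensities are clipped with a message, not silently
  neg <- EventTable(cbind(AF647 = c(-5, 10), AF700 = c(1, 1),
                          APCCy7 = c(1, 1)))
  expect_message(mneg <- mergeMBChannel(neg, map), "clipped")
  expect_equal(unname(exprs(mneg)[, "MBmerged"]), c(2, 12))

  # merge-then-gate equals gate-then-merge
  s <- SampleSpec("c", c(neutrophil = 300, T = 300), timeH = 1,
                  moi = 10, seed = 17)
  et <- renderEvents(s)
  g <- defaultGates()$granulocyte
  a <- scatterGate(mergeMBChannel(et, map), g)
  b <- mergeMBChannel(scatterGate(et, g), map)
  expect_identical(exprs(a), exprs(b))
})

test_that("geometric MFI: floored log-mean with scale equivariance", {
  expect_equal(geometricMFI(c(10, 1000)), 100)
  expect_equal(geometricMFI(rep(42, 3)), 42)
  set.seed(23)
  v <- rlnorm(500, 4, 0.6) + 2
  expect_equal(geometricMFI(3 * v), 3 * geometricMFI(v),
               tolerance = 1e-9)
  expect_error(geometricMFI(numeric(0)), "zero events")
  expect_warning(f <- geometricMFI(c(0.1, 0.5, 1)), "floor")
  expect_equal(f, 1)
})

test_that("FMO threshold matches the analytic quantile and bounds its
           own control", {
  set.seed(29)
  n <- 1e5
  ctl <- EventTable(cbind(MBmerged = rlnorm(n, 3, 0.5)))
  g <- fmoThreshold(ctl, "MBmerged", 99.5)
  expect_identical(g@provenance, "FMO-derived")
  analytic <- qlnorm(0.995, 3, 0.5)
  expect_lt(abs(g@bounds - analytic) / analytic, 0.02)

  # applying the gate back to its own control: at most ~0.5% MB-high
  cls <- classifyMB(ctl, g)
  expect_lte(cls$counts[["MBhi"]] / n, 0.005 + 3 * sqrt(0.005 / n))

  # percentile 100 is the control maximum
  g100 <- fmoThreshold(ctl, "MBmerged", 100)
  expect_equal(unname(g100@bounds), max(exprs(ctl)[, "MBmerged"]))

  expect_error(fmoThreshold(ctl[1:150], "MBmerged"), "200 events")
  expect_error(fmoThreshold(ctl, "nope"), "nope")
})

test_that("MB-high classification is an exhaustive, order-independent
           partition", {
  set.seed(31)
  et <- EventTable(cbind(MBmerged = rlnorm(1000, 4, 1)))
  g <- thresholdGate("MBmerged", 60)
  cls <- classifyMB(et, g)
  expect_equal(sum(cls$counts), 1000)
  expect_identical(length(cls$labels), 1000L)

  shuffled <- et[sample(1000)]
  expect_identical(classifyMB(shuffled, g)$counts, cls$counts)

  empty <- classifyMB(et[integer(0)], g)
  expect_equal(unname(empty$counts), c(0, 0))
})

test_that("measured red-shift ratio equals the spectral prediction for
           noise-free events and is brightness-invariant", {
  m <- defaultSpectralModel()
  for (rho in c(0, 0.25, 0.5, 0.75, 1)) {
    et <- makePureEvents(m, rho)
    expect_equal(redshiftRatio(et, map), predictRedshiftRatio(m, rho),
                 tolerance = 1e-6)
  }
  expect_gt(redshiftRatio(makePureEvents(m, 0.8), map),
            redshiftRatio(makePureEvents(m, 0.2), map))

  # overall brightness cancels
  et <- makePureEvents(m, 0.4)
  bright <- EventTable(exprs(et) * 17)
  expect_equal(redshiftRatio(bright, map), redshiftRatio(et, map),
               tolerance = 1e-9)

  dark <- EventTable(cbind(AF647 = rep(0.5, 10), AF700 = rep(1, 10),
                           APCCy7 = rep(2, 10)))
  expect_error(suppressWarnings(redshiftRatio(dark, map)), "floor")
})

test_that("scatter gating: identity, emptiness, and granulocyte purity", {
  s <- SampleSpec("scg", c(neutrophil = 2000, monocyte = 300, T = 400,
                           B = 200, NK = 200, eosinophil = 50),
                  compartment = "blood", label = "none", moi = 0,
                  seed = 47)
  et <- renderEvents(s)
  all <- scatterGate(et, boxGate(c("FSC", "SSC"), lo = c(0, 0),
                                 hi = c(1e9, 1e9)))
  expect_identical(nrow(all), nrow(et))
  expect_warning(none <- scatterGate(et, boxGate(c("FSC", "SSC"),
                                                 lo = c(1e8, 1e8),
                                                 hi = c(2e8, 2e8))),
                 "excludes all")
  expect_identical(nrow(none), 0L)

  gran <- scatterGate(et, defaultGates()$granulocyte)
  purity <- mean(eventTruth(gran)$population %in%
                   c("neutrophil", "eosinophil"))
  expect_gte(purity, 0.9)

  # rule-based population calls agree with the ground truth
  calls <- assignPopulations(et)
  tr <- eventTruth(et)$population
  lineage <- ifelse(tr %in% c("T", "B", "NK"), "lymphocyte", tr)
  expect_gt(mean(calls == lineage), 0.95)
})
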