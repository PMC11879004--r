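pops <- cellPopulations()

test_that("ingestion counts follow the Poisson uptake law", {
  neu <- pops$neutrophil

  expect_true(all(simulateBacteriaPerCell(neu, 1, 0, n = 100,
                                          seed = 1) == 0))
  expect_true(all(simulateBacteriaPerCell(pops$T, 2, 100, n = 100,
                                          seed = 1) == 0))

  # cytochalasin B reduces mean uptake to about 2% of vehicle
  n <- 1e4
  veh <- simulateBacteriaPerCell(neu, 1, 30, "none", n = n, seed = 11)
  cyt <- simulateBacteriaPerCell(neu, 1, 30, "cytochalasinB", n = n,
                                 seed = 12)
  ratio <- mean(cyt) / mean(veh)
  se <- sqrt(var(cyt) / n) / mean(veh)
  expect_lt(abs(ratio - 0.02), 3 * se + 1e-4)

  # mean counts nondecreasing in both time and MOI (4 x 4 grid)
  times <- c(0.25, 0.5, 1, 2); mois <- c(1, 3, 10, 30)
  mgrid <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    mgrid[i, j] <- mean(simulateBacteriaPerCell(neu, times[i], mois[j],
                                                n = 5000,
                                                seed = 100 + 10 * i + j))
  expect_true(all(apply(mgrid, 2, diff) > -1e-9))
  expect_true(all(apply(mgrid, 1, diff) > -1e-9))
})

test_that("oxidation kinetics: first-order approach, zero under CGD", {
  expect_equal(simulateOxidation(c(0, 1, 2), kOx = 0, timeH = 3),
               c(0, 0, 0))
  expect_equal(simulateOxidation(0, kOx = 1e6, timeH = 1), 1,
               tolerance = 1e-12)
  tIngest <- 1
  rhoAt <- function(t) simulateOxidation(tIngest, kOx = 0.8, timeH = t)
  expect_true(all(diff(vapply(c(1, 2, 4, 8, 24), rhoAt, 0)) > 0))
})

test_that("rendered samples reproduce the population biology", {
  mix <- c(neutrophil = 1500, monocyte = 800, macrophage = 800, T = 500,
           B = 300, NK = 300)
  s <- SampleSpec("bio", mix, timeH = 1, moi = 30, seed = 21)
  et <- renderEvents(s)
  tr <- eventTruth(et)
  meanLoad <- tapply(tr$bacteria_count, tr$population, mean)
  expect_gt(meanLoad[["neutrophil"]], meanLoad[["monocyte"]])
  expect_gt(meanLoad[["macrophage"]], meanLoad[["monocyte"]])
  expect_gt(meanLoad[["monocyte"]],
            max(meanLoad[["T"]], meanLoad[["B"]], meanLoad[["NK"]]))
  expect_equal(as.numeric(meanLoad[c("T", "B", "NK")]), c(0, 0, 0))

  # genotype contrast at 180 min: healthy > carrier > affected (= 0)
  rhoOf <- function(g, seed) {
    sp <- SampleSpec(g, c(neutrophil = 2000), timeH = 3, moi = 10,
                     genotype = g, seed = seed)
    tr <- eventTruth(renderEvents(sp))
    mean(tr$rho[tr$bacteria_count > 0])
  }
  h <- rhoOf("healthy", 31)
  c2 <- rhoOf("CGD_carrier", 32)
  a <- rhoOf("CGD_affected", 33)
  expect_gt(h, c2)
  expect_gt(c2, a)
  expect_equal(a, 0)
  # lyonization: carrier mean is about half the healthy mean
  expect_lt(abs(c2 / h - 0.5), 0.1)
})

test_that("rendering is deterministic and the MB label leaves every
           non-MB channel untouched", {
  s <- SampleSpec("det", c(neutrophil = 400, T = 200), timeH = 1,
                  moi = 10, seed = 5)
  a <- renderEvents(s)
  b <- renderEvents(s)
  expect_identical(exprs(a), exprs(b))
  expect_identical(eventTruth(a), eventTruth(b))

  # MBEC vs unlabeled E. coli: identical activation markers (same seed),
  # MB signal only in the labeled tube
  lab <- s
  unl <- SampleSpec("det", c(neutrophil = 400, T = 200), timeH = 1,
                    moi = 10, label = "unlabeled_E_coli", seed = 5)
  etL <- renderEvents(lab); etU <- renderEvents(unl)
  for (mk in c("CD11b", "CD66b", "CD45", "CD62L", "FSC", "SSC"))
    expect_identical(exprs(etL)[, mk], exprs(etU)[, mk])
  expect_gt(mean(exprs(etL)[, "AF647"]), 5 * mean(exprs(etU)[, "AF647"]))

  # no label, no autofluorescence, no noise: MB channels exactly zero
  clean <- SampleSpec("z", c(neutrophil = 50), label = "none", seed = 1)
  etZ <- renderEvents(clean, pops = zeroAFPops(), noiseCV = 0)
  expect_true(all(exprs(etZ)[, c("AF647", "AF700", "APCCy7")] == 0))

  # permeabilization reduces MB load tenfold
  perm <- SampleSpec("p", c(neutrophil = 2000), timeH = 1, moi = 30,
                     perturbation = "permeabilization", seed = 6)
  intact <- SampleSpec("i", c(neutrophil = 2000), timeH = 1, moi = 30,
                       seed = 6)
  mfiP <- geometricMFI(exprs(renderEvents(perm,
                                          pops = zeroAFPops()))[, "AF647"])
  mfiI <- geometricMFI(exprs(renderEvents(intact,
                                          pops = zeroAFPops()))[, "AF647"])
  expect_lt(mfiP / mfiI, 0.25)

  expect_error(renderEvents(SampleSpec("bad", c(goblin = 10))),
               "unknown population")
})

test_that("blister neutrophils out-fluoresce matched blood neutrophils", {
  bl <- SampleSpec("bl", c(neutrophil = 1000), compartment = "blister",
                   timeH = 24, moi = 0.27, seed = 41)
  bd <- SampleSpec("bd", c(neutrophil = 1000), compartment = "blood",
                   timeH = 24, moi = 0.27, label = "none", seed = 42)
  map <- defaultChannelMap()
  mbOf <- function(sp) {
    et <- mergeMBChannel(renderEvents(sp), map)
    median(exprs(et)[, map@merged])
  }
  expect_gt(mbOf(bl), mbOf(bd))
})

test_that("generated studies have the designed layout and are
           seed-deterministic", {
  dir <- cachedStudy("exvivo", seed = 1)
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  expect_identical(sum(meta$label == "unlabeled_E_coli"), 1L)
  expect_setequal(meta$time_h[meta$label == "MBEC"],
                  c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(file.exists(file.path(dir, meta$file))))

  iv <- read.delim(file.path(cachedStudy("invivo", seed = 1),
                             "metadata.tsv"))
  blisters <- iv[iv$compartment == "blister" & iv$label == "MBEC", ]
  expect_identical(nrow(blisters), 38L)
  perTime <- table(blisters$time_h)
  expect_setequal(as.numeric(names(perTime)), c(3, 5, 7, 9, 24))
  expect_true(all(perTime %in% 7:8))
  # endotoxin clearance column is strictly decreasing in time
  endo <- tapply(blisters$endotoxin_EU_mL, blisters$time_h, mean)
  expect_true(all(diff(endo[order(as.numeric(names(endo)))]) < 0))

  # identical seed, byte-identical ground truth
  d1 <- file.path(tempdir(), "detA"); d2 <- file.path(tempdir(), "detB")
  generateStudy("moi", d1, seed = 99)
  generateStudy("moi", d2, seed = 99)
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.tsv"))),
                   unname(tools::md5sum(file.path(d2, "truth.tsv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "metadata.tsv"))),
                   unname(tools::md5sum(file.path(d2, "metadata.tsv"))))

  # an absent population yields a valid file without it
  sp <- SampleSpec("nolymph", c(neutrophil = 100, T = 0), seed = 1)
  et <- renderEvents(sp)
  expect_false("T" %in% eventTruth(et)$population)
  expect_identical(nrow(et), 100L)
})
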