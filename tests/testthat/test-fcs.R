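test_that("FCS 3.1 files round-trip events, channels and annotations", {
  s <- SampleSpec("rt1", c(neutrophil = 300, T = 100), timeH = 0.5,
                  moi = 10, seed = 7)
  et <- renderEvents(s)
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, f)
  back <- readFCS(f)

  expect_equal(nrow(back), nrow(et))
  expect_identical(channelNames(back), channelNames(et))
  # 32-bit float storage: values agree to single precision
  expect_equal(exprs(back), exprs(et), tolerance = 1e-6)
  expect_identical(back@metadata$sample_id, "rt1")
  expect_identical(acquisitionMode(back), "conventional")
  # latent truth never reaches the FCS file
  expect_identical(nrow(eventTruth(back)), 0L)

  # spectral mode round-trips its binned channels and mode flag
  ssp <- SampleSpec("rt2", c(neutrophil = 100), mode = "spectral",
                    seed = 8)
  et2 <- renderEvents(ssp)
  f2 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et2, f2)
  back2 <- readFCS(f2)
  expect_identical(acquisitionMode(back2), "spectral")
  expect_true(all(grepl("nm$", grep("^MB_", channelNames(back2),
                                    value = TRUE))))
})

test_that("tabular fallback and FCS of the same sample agree", {
  s <- SampleSpec("eq", c(neutrophil = 400), timeH = 1, moi = 10,
                  seed = 3)
  et <- renderEvents(s)
  ffcs <- withr::local_tempfile(fileext = ".fcs")
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeFCS(et, ffcs)
  writeEventsTSV(et, ftsv)
  a <- readEvents(ffcs)
  b <- readEvents(ftsv)
  expect_equal(nrow(a), nrow(b))
  for (ch in c("AF647", "APCCy7", "FSC")) {
    expect_equal(geometricMFI(exprs(a)[, ch]),
                 geometricMFI(exprs(b)[, ch]), tolerance = 1e-5)
  }
})

test_that("unreadable inputs fail loudly, never silently partially", {
  s <- SampleSpec("tr", c(neutrophil = 200), seed = 2)
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(renderEvents(s), f)

  # truncate the data segment
  raw <- readBin(f, "raw", file.info(f)$size)
  half <- withr::local_tempfile(fileext = ".fcs")
  writeBin(raw[seq_len(length(raw) - 2000)], half)
  expect_error(readFCS(half), "truncated")

  expect_error(readFCS(withr::local_tempfile(fileext = ".fcs")),
               "no such file")
  junk <- withr::local_tempfile(fileext = ".fcs")
  writeLines("not fcs at all", junk)
  expect_error(readFCS(junk), "FCS")

  # a channel map names the missing channel
  noMB <- EventTable(cbind(FSC = 1:5, SSC = 1:5))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeEventsTSV(noMB, ftsv)
  expect_error(readEvents(ftsv, defaultChannelMap()), "AF647")
})
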