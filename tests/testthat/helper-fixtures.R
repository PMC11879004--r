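# Shared fixtures: all synthetic, generated in code at test time.

# Events rendered at one fixed oxidized fraction with zero noise and no
# autofluorescence, built by integrating the mixed spectrum directly
# (mix-then-integrate), independently of the model's basis-matrix path
# (integrate-then-mix). Loads vary per event; the red-shift ratio of
# such a table is load-free.
makePureEvents <- function(model, rho, n = 50, loads = NULL) {
  if (is.null(loads)) loads <- seq(100, 2000, length.out = n)
  mix <- mixSpectra(model, rho)
  vals <- vapply(modelChannels(model),
                 function(ch) loads * bandIntegral(mix, ch), numeric(n))
  EventTable(vals)
}

# A population with no autofluorescence, for exact zero-signal checks.
zeroAFPops <- function() {
  pops <- cellPopulations()
  for (nm in names(pops)) pops[[nm]]@autofluorescence[] <- 0
  pops
}

# Session-cached generated studies (each design/seed/mode generated once).
.studyCache <- new.env(parent = emptyenv())
cachedStudy <- function(design, seed = 1L, mode = "conventional") {
  key <- paste(design, seed, mode, sep = "_")
  if (is.null(.studyCache[[key]])) {
    dir <- file.path(tempdir(), paste0("study_", key))
    generateStudy(design, dir, seed = seed, mode = mode)
    .studyCache[[key]] <- dir
  }
  .studyCache[[key]]
}

.runCache <- new.env(parent = emptyenv())
cachedRun <- function(design, seed = 1L, mode = "conventional") {
  key <- paste(design, seed, mode, sep = "_")
  if (is.null(.runCache[[key]])) {
    dir <- cachedStudy(design, seed, mode)
    out <- file.path(tempdir(), paste0("run_", key))
    .runCache[[key]] <- runStudy(dir, out)
  }
  .runCache[[key]]
}

# random valid spectrum on an increasing grid
randomSpectrum <- function(npts = 30) {
  w <- sort(runif(npts, 600, 900))
  while (any(diff(w) <= 0)) w <- sort(runif(npts, 600, 900))
  EmissionSpectrum(w, runif(npts, 0, 10))
}
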