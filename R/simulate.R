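## Synthetic spectral-cytometry event generator.
##
## Forward model per cell: Poisson bacterial ingestion (rate x MOI x
## exposure kinetics) -> first-order oxidation of internalized MB during
## phagolysosomal residence -> per-channel band integrals of the
## two-state mixture scaled by MB load -> plus autofluorescence -> times
## multiplicative log-normal noise. Ex vivo cocultures see a single
## bacterial bolus with saturating uptake kinetics; blister neutrophils
## arrive continuously and encounter bacteria throughout their dwell
## time.

.LOAD_PER_BACTERIUM <- 300   # a.u. of integrated MB emission per MBEC;
                             # places a single ingested bacterium well
                             # above cellular autofluorescence in the
                             # red channels, as observed for MBEC
.DEFAULT_NOISE_CV <- 0.25    # multiplicative log-normal CV
.T_HALF_H <- 0.5             # h, half-saturation of coculture uptake
.CYTB_FACTOR <- 0.02         # residual uptake under cytochalasin B
.PERM_FACTOR <- 0.1          # residual MB after permeabilization
.MARKER_SDLOG <- 0.3
.SPECTRAL_BIN_NM <- 5

#' SampleSpec: one simulated cytometry tube
#'
#' @slot sampleId unique sample identifier.
#' @slot mode \code{"conventional"} or \code{"spectral"}.
#' @slot compartment \code{"coculture"}, \code{"blood"} or
#'   \code{"blister"}.
#' @slot timeH hours since MBEC exposure (coculture) or intradermal
#'   injection (blister).
#' @slot moi multiplicity of infection: bacteria per cell in coculture,
#'   or the effective local bacterial density for blister cells.
#' @slot label \code{"MBEC"}, \code{"unlabeled_E_coli"} or
#'   \code{"none"}; unlabeled bacteria drive identical
#'   activation-marker shifts but contribute no MB signal.
#' @slot labelConcPct MB labeling concentration used for the MBEC
#'   (percent w/v; 1, 0.5 or 0.3); MB load scales linearly with it.
#' @slot genotype \code{"healthy"}, \code{"CGD_affected"} (k_ox = 0) or
#'   \code{"CGD_carrier"} (exactly half of each population's cells have
#'   k_ox = 0, modeling X-chromosome lyonization).
#' @slot perturbation \code{"none"}, \code{"cytochalasinB"}
#'   (phagocytosis inhibited to 2 percent) or \code{"permeabilization"}
#'   (MB load reduced to 10 percent).
#' @slot nEvents named integer vector: events per population.
#' @slot seed integer RNG seed for this sample.
#' @slot volunteer,site donor/replicate annotations.
#' @exportClass SampleSpec
setClass("SampleSpec",
  representation(sampleId = "character", mode = "character",
                 compartment = "character", timeH = "numeric",
                 moi = "numeric", label = "character",
                 labelConcPct = "numeric", genotype = "character",
                 perturbation = "character", nEvents = "numeric",
                 seed = "integer", volunteer = "character",
                 site = "character"))

setValidity("SampleSpec", function(object) {
  if (!object@mode %in% c("conventional", "spectral"))
    return("mode must be 'conventional' or 'spectral'")
  if (!object@compartment %in% c("coculture", "blood", "blister"))
    return("compartment must be coculture, blood or blister")
  if (object@timeH < 0) return("timeH must be >= 0")
  if (object@moi < 0) return("moi must be >= 0")
  if (!object@label %in% c("MBEC", "unlabeled_E_coli", "none"))
    return("label must be MBEC, unlabeled_E_coli or none")
  if (object@labelConcPct < 0) return("labelConcPct must be >= 0")
  if (!object@genotype %in% c("healthy", "CGD_affected", "CGD_carrier"))
    return("unknown genotype")
  if (!object@perturbation %in% c("none", "cytochalasinB",
                                  "permeabilization"))
    return("unknown perturbation")
  if (is.null(names(object@nEvents)) || any(object@nEvents < 0))
    return("nEvents must be a named nonnegative vector")
  TRUE
})

#' Construct a SampleSpec
#'
#' @param sampleId sample identifier.
#' @param nEvents named vector of events per population, e.g.
#'   \code{c(neutrophil = 2000, T = 500)}.
#' @param mode,compartment,timeH,moi,label,labelConcPct,genotype,perturbation
#'   see \linkS4class{SampleSpec}.
#' @param seed integer RNG seed.
#' @param volunteer,site optional donor/replicate annotations.
#' @return A \linkS4class{SampleSpec}.
#' @export
SampleSpec <- function(sampleId, nEvents, mode = "conventional",
                       compartment = "coculture", timeH = 1, moi = 10,
                       label = "MBEC", labelConcPct = 1,
                       genotype = "healthy", perturbation = "none",
                       seed = 1L, volunteer = "", site = "") {
  new("SampleSpec", sampleId = sampleId, mode = mode,
      compartment = compartment, timeH = timeH, moi = moi, label = label,
      labelConcPct = labelConcPct, genotype = genotype,
      perturbation = perturbation, nEvents = nEvents,
      seed = as.integer(seed), volunteer = volunteer, site = site)
}

setMethod("show", "SampleSpec", function(object) {
  cat(sprintf(
    "SampleSpec '%s': %s %s, t = %g h, MOI %g, %s, %s, %d events\n",
    object@sampleId, object@mode, object@compartment, object@timeH,
    object@moi, object@label, object@genotype, sum(object@nEvents)))
})

#' Simulate per-cell ingested bacteria counts
#'
#' Counts are Poisson with mean \code{lambda = phagocyticRate * moi *
#' f(exposure)}, where \code{f} is the saturating time transform
#' \code{t / (t + tHalf)} for a single-bolus coculture, or linear
#' exposure time for continuous in-tissue encounter. Cytochalasin B
#' multiplies \code{lambda} by 0.02. The mean is nondecreasing in both
#' exposure time and MOI.
#'
#' @param pop a \linkS4class{CellPopulationSpec}.
#' @param timeH exposure time in hours (scalar, or one value per cell).
#' @param moi multiplicity of infection.
#' @param perturbation \code{"none"}, \code{"cytochalasinB"} or
#'   \code{"permeabilization"} (the latter does not affect ingestion).
#' @param n number of cells (defaults to \code{length(timeH)}).
#' @param saturating use the saturating bolus kinetics (default) or
#'   linear continuous-encounter kinetics.
#' @param tHalf half-saturation time (h) of the bolus kinetics.
#' @param seed optional RNG seed.
#' @return Integer vector of per-cell bacteria counts.
#' @examples
#' simulateBacteriaPerCell(cellPopulations()$T, 1, 30, n = 5)  # all 0
#' @export
simulateBacteriaPerCell <- function(pop, timeH, moi,
                                    perturbation = "none",
                                    n = length(timeH), saturating = TRUE,
                                    tHalf = .T_HALF_H, seed = NULL) {
  stopifnot(is(pop, "CellPopulationSpec"), all(timeH >= 0), moi >= 0)
  if (!is.null(seed)) set.seed(seed)
  tEff <- if (saturating) timeH / (timeH + tHalf) else timeH
  lambda <- pop@phagocyticRate * moi * tEff
  if (perturbation == "cytochalasinB") lambda <- lambda * .CYTB_FACTOR
  if (length(lambda) == 1L) lambda <- rep(lambda, n)
  rpois(n, lambda)
}

#' Oxidized fraction of internalized MB after phagolysosomal residence
#'
#' First-order approach to full oxidation:
#' \code{rho = 1 - exp(-kOx * (timeH - ingestionTime))}. With
#' \code{kOx = 0} (CGD-affected cells) the result is exactly 0.
#'
#' @param ingestionTime per-cell ingestion time (h since exposure
#'   start); must not exceed \code{timeH}.
#' @param kOx oxidation rate (1/h), scalar or per cell.
#' @param timeH current time (h).
#' @return Per-cell oxidized fraction in \code{[0, 1]}.
#' @export
simulateOxidation <- function(ingestionTime, kOx, timeH) {
  stopifnot(all(kOx >= 0), all(ingestionTime <= timeH + 1e-12))
  residence <- pmax(timeH - ingestionTime, 0)
  1 - exp(-kOx * residence)
}

# mean-1 multiplicative log-normal noise
.lnNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# spectral-mode wavelength bins as BandPassChannel list
.spectralBins <- function(model, width = .SPECTRAL_BIN_NM) {
  grid <- model@reduced@wavelength
  lo <- seq(min(grid), max(grid) - width, by = width)
  setNames(lapply(lo, function(l)
    BandPassChannel(sprintf("MB_%d_%dnm", l, l + width), l, l + width)),
    sprintf("MB_%d_%dnm", lo, lo + width))
}

#' Render the events of one simulated sample
#'
#' Draws per-cell bacteria counts and oxidation states, then renders
#' scatter, MB-detecting channels (three band channels in conventional
#' mode, wavelength bins in spectral mode) and surface markers, with
#' additive autofluorescence and multiplicative log-normal noise.
#' Activation-marker shifts depend only on bacterial contact, never on
#' the MB label, so MBEC and unlabeled-E. coli samples are
#' distributionally identical in every channel except the MB signal.
#'
#' @param sample a \linkS4class{SampleSpec}.
#' @param model a \linkS4class{SpectralModel}.
#' @param pops named list of \linkS4class{CellPopulationSpec}; every
#'   population named in \code{sample@nEvents} must be present.
#' @param noiseCV multiplicative noise CV (default 0.25).
#' @param loadPerBacterium integrated MB emission per ingested bacterium
#'   at 1 percent labeling (a.u.).
#' @return An \linkS4class{EventTable} with ground-truth columns
#'   \code{population}, \code{bacteria_count}, \code{rho},
#'   \code{exposure_h}.
#' @examples
#' s <- SampleSpec("demo", c(neutrophil = 100, T = 50), seed = 1)
#' renderEvents(s)
#' @export
renderEvents <- function(sample, model = defaultSpectralModel(),
                         pops = cellPopulations(),
                         noiseCV = .DEFAULT_NOISE_CV,
                         loadPerBacterium = .LOAD_PER_BACTERIUM) {
  stopifnot(is(sample, "SampleSpec"), is(model, "SpectralModel"))
  wanted <- names(sample@nEvents)[sample@nEvents > 0]
  unknown <- setdiff(wanted, names(pops))
  if (length(unknown))
    stop("unknown population name(s): ", paste(unknown, collapse = ", "))
  set.seed(sample@seed)

  conventional <- sample@mode == "conventional"
  if (conventional) {
    chans <- modelChannels(model)
    B <- .basisBandMatrix(model, chans)
  } else {
    bins <- .spectralBins(model)
    B <- .basisBandMatrix(model, bins)
    binMid <- vapply(bins, function(b) (b@lo + b@hi) / 2, 0)
    afShape <- exp(-(binMid - min(binMid)) / 60)
    afShape <- afShape / sum(afShape)
  }

  blocks <- list(); truths <- list()
  for (nm in wanted) {
    pop <- pops[[nm]]
    n <- as.integer(sample@nEvents[[nm]])

    # exposure to bacteria: single bolus for the whole coculture time,
    # uniform arrival for blister infiltration, none in blood
    exposure <- switch(sample@compartment,
      coculture = rep(sample@timeH, n),
      blister = runif(n, 0, sample@timeH),
      blood = rep(0, n))
    moiEff <- if (sample@label == "none") 0 else sample@moi
    counts <- simulateBacteriaPerCell(pop, exposure, moiEff,
      perturbation = sample@perturbation, n = n,
      saturating = sample@compartment == "coculture")

    # oxidation: ingestion uniform over each cell's exposure window;
    # CGD genotypes modify k_ox (carriers: exactly half the cells)
    kox <- rep(pop@oxidationRate, n)
    if (sample@genotype == "CGD_affected") kox[] <- 0
    if (sample@genotype == "CGD_carrier" && n > 0)
      kox[seq_len(floor(n / 2))] <- 0
    residence <- runif(n, 0, exposure)
    rho <- ifelse(counts > 0, 1 - exp(-kox * residence), 0)

    load <- if (sample@label == "MBEC")
      loadPerBacterium * counts * sample@labelConcPct else rep(0, n)
    if (sample@perturbation == "permeabilization")
      load <- load * .PERM_FACTOR

    # MB-detecting channels: load x mixture band mass + autofluorescence
    if (conventional) {
      mb <- vapply(seq_along(chans), function(j) {
        sig <- load * ((1 - rho) * B["reduced", j] +
                         rho * B["oxidized", j])
        (sig + pop@autofluorescence[[names(chans)[j]]]) *
          .lnNoise(n, noiseCV)
      }, numeric(n))
      if (n == 1L) mb <- matrix(mb, nrow = 1)
      colnames(mb) <- names(chans)
    } else {
      afTot <- sum(pop@autofluorescence)
      mb <- vapply(seq_along(bins), function(j) {
        sig <- load * ((1 - rho) * B["reduced", j] +
                         rho * B["oxidized", j])
        (sig + afTot * afShape[j]) * .lnNoise(n, noiseCV)
      }, numeric(n))
      if (n == 1L) mb <- matrix(mb, nrow = 1)
      colnames(mb) <- names(bins)
    }

    fsc <- rlnorm(n, log(pop@scatter[["fsc"]]), pop@scatter[["sdlog"]])
    ssc <- rlnorm(n, log(pop@scatter[["ssc"]]), pop@scatter[["sdlog"]])

    # markers: baseline x context shift x per-cell uptake modulation
    fc <- if (sample@compartment == "blister") .BLISTER_FC
          else if (moiEff > 0) .ACTIVATION_FC
          else setNames(rep(1, length(.ACTIVATION_FC)),
                        names(.ACTIVATION_FC))
    capped <- pmin(counts, .UPTAKE_CAP)
    mk <- vapply(names(pop@markers), function(m) {
      mu <- log(pop@markers[[m]] * fc[[m]]) + .UPTAKE_BETA[[m]] * capped
      rlnorm(n, mu, .MARKER_SDLOG)
    }, numeric(n))
    if (n == 1L) mk <- matrix(mk, nrow = 1,
                              dimnames = list(NULL, names(pop@markers)))

    blocks[[nm]] <- cbind(FSC = fsc, SSC = ssc, mb, mk)
    truths[[nm]] <- data.frame(population = rep(nm, n),
                               bacteria_count = counts, rho = rho,
                               exposure_h = exposure)
  }
  ex <- do.call(rbind, blocks)
  rownames(ex) <- NULL
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  EventTable(ex, truth = truth, mode = sample@mode,
             metadata = list(sample_id = sample@sampleId,
                             compartment = sample@compartment,
                             time_h = sample@timeH, moi = sample@moi,
                             label = sample@label,
                             genotype = sample@genotype,
                             perturbation = sample@perturbation,
                             label_concentration_pct = sample@labelConcPct,
                             volunteer = sample@volunteer,
                             site = sample@site, seed = sample@seed))
}
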