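#' @import methods
#' @importFrom stats approx dlnorm quantile rlnorm rpois runif sd cor
#'   coef lm qlnorm setNames median
#' @importFrom utils read.delim write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## EmissionSpectrum
## ---------------------------------------------------------------------------

#' EmissionSpectrum: a wavelength-gridded fluorescence (or absorbance) curve
#'
#' Holds one spectrum sampled on a strictly increasing wavelength grid with
#' nonnegative intensities in arbitrary units. This is the unit that
#' normalization, peak finding, band integration and unmixing operate on.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm (length
#'   at least 2).
#' @slot intensity numeric, nonnegative intensities, same length as
#'   \code{wavelength}.
#' @aliases EmissionSpectrum
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(wavelength = "numeric", intensity = "numeric"))

setValidity("EmissionSpectrum", function(object) {
  w <- object@wavelength
  y <- object@intensity
  if (length(w) != length(y))
    return("'wavelength' and 'intensity' must have the same length")
  if (length(w) < 2L)
    return("a spectrum needs at least 2 grid points")
  if (anyNA(w) || anyNA(y))
    return("NA values are not allowed")
  if (any(diff(w) <= 0))
    return("'wavelength' must be strictly increasing")
  if (any(y < 0))
    return("'intensity' must be nonnegative")
  TRUE
})

#' Construct an EmissionSpectrum
#'
#' @param wavelength strictly increasing wavelength grid (nm).
#' @param intensity nonnegative intensities (a.u.), same length.
#' @return An \linkS4class{EmissionSpectrum}.
#' @examples
#' s <- EmissionSpectrum(650:700, rep(1, 51))
#' @export
EmissionSpectrum <- function(wavelength, intensity) {
  new("EmissionSpectrum", wavelength = as.numeric(wavelength),
      intensity = as.numeric(intensity))
}

#' @describeIn EmissionSpectrum-class wavelength grid accessor (nm)
#' @param x,object an \code{EmissionSpectrum}
#' @export
wavelength <- function(x) x@wavelength

#' @describeIn EmissionSpectrum-class intensity accessor (a.u.)
#' @export
intensity <- function(x) x@intensity

setMethod("show", "EmissionSpectrum", function(object) {
  w <- object@wavelength
  cat("EmissionSpectrum:", length(w), "points,",
      sprintf("%g-%g nm, total intensity %.4g\n",
              min(w), max(w), sum(object@intensity)))
})

#' @describeIn EmissionSpectrum-class number of grid points
#' @export
setMethod("length", "EmissionSpectrum", function(x) length(x@wavelength))

## ---------------------------------------------------------------------------
## BandPassChannel
## ---------------------------------------------------------------------------

#' BandPassChannel: a detector band-pass window
#'
#' A named detection window \code{[lo, hi]} in nm with a multiplicative
#' detector gain (the model for detector voltage).
#'
#' @slot name channel identifier, e.g. \code{"AF647"}.
#' @slot lo,hi window bounds in nm, \code{lo < hi}.
#' @slot gain positive multiplicative gain.
#' @exportClass BandPassChannel
setClass("BandPassChannel",
  representation(name = "character", lo = "numeric", hi = "numeric",
                 gain = "numeric"))

setValidity("BandPassChannel", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single nonempty string")
  if (!(length(object@lo) == 1L && length(object@hi) == 1L &&
        is.finite(object@lo) && is.finite(object@hi)))
    return("'lo' and 'hi' must be single finite numbers")
  if (object@lo >= object@hi) return("'lo' must be < 'hi'")
  if (length(object@gain) != 1L || !is.finite(object@gain) ||
      object@gain <= 0)
    return("'gain' must be a single positive number")
  TRUE
})

#' Construct a BandPassChannel
#'
#' @param name channel identifier.
#' @param lo,hi detection window bounds (nm).
#' @param gain multiplicative detector gain (default 1).
#' @return A \linkS4class{BandPassChannel}.
#' @examples
#' BandPassChannel("AF647", 655, 685)
#' @export
BandPassChannel <- function(name, lo, hi, gain = 1) {
  new("BandPassChannel", name = as.character(name), lo = as.numeric(lo),
      hi = as.numeric(hi), gain = as.numeric(gain))
}

setMethod("show", "BandPassChannel", function(object) {
  cat(sprintf("BandPassChannel '%s': %g-%g nm, gain %g\n",
              object@name, object@lo, object@hi, object@gain))
})

## ---------------------------------------------------------------------------
## SpectralModel
## ---------------------------------------------------------------------------

#' SpectralModel: two-state methylene blue emission model
#'
#' Methylene blue emission is modeled as a mixture of two fixed basis
#' spectra sharing one wavelength grid: a reduced (unoxidized,
#' intracellular) state peaking at the primary emission peak and an
#' oxidation-shifted state peaking at the far-red shoulder. Both bases are
#' stored sum-normalized. The model also carries the dye's absorbance peak
#' and the detector band-pass channels used for conventional cytometry.
#'
#' @slot reduced,oxidized sum-normalized \linkS4class{EmissionSpectrum}
#'   bases on a common grid; the oxidized mode lies at a longer
#'   wavelength than the reduced mode.
#' @slot absorbancePeak wavelength of maximal absorbance (nm).
#' @slot channels named list of \linkS4class{BandPassChannel}.
#' @seealso [defaultSpectralModel()]
#' @exportClass SpectralModel
setClass("SpectralModel",
  representation(reduced = "EmissionSpectrum", oxidized = "EmissionSpectrum",
                 absorbancePeak = "numeric", channels = "list"))

setValidity("SpectralModel", function(object) {
  r <- object@reduced; o <- object@oxidized
  if (!isTRUE(all.equal(r@wavelength, o@wavelength)))
    return("reduced and oxidized bases must share one wavelength grid")
  if (abs(sum(r@intensity) - 1) > 1e-9 || abs(sum(o@intensity) - 1) > 1e-9)
    return("basis spectra must be stored sum-normalized (sum to 1)")
  if (findPeak(o) <= findPeak(r))
    return("oxidized basis must peak at a longer wavelength than reduced")
  if (length(object@absorbancePeak) != 1L)
    return("'absorbancePeak' must be a single wavelength")
  if (!all(vapply(object@channels, is, TRUE, "BandPassChannel")))
    return("'channels' must be a list of BandPassChannel objects")
  TRUE
})

setMethod("show", "SpectralModel", function(object) {
  cat("SpectralModel (two-state methylene blue)\n")
  cat(sprintf("  reduced peak:  %g nm\n", findPeak(object@reduced)))
  cat(sprintf("  oxidized peak: %g nm\n", findPeak(object@oxidized)))
  cat(sprintf("  absorbance peak: %g nm\n", object@absorbancePeak))
  cat("  channels:", paste(vapply(object@channels, function(c)
    sprintf("%s[%g-%g]", c@name, c@lo, c@hi), ""), collapse = " "), "\n")
})

#' @describeIn SpectralModel-class reduced-state basis spectrum
#' @param object a \code{SpectralModel}
#' @export
reducedBasis <- function(object) object@reduced

#' @describeIn SpectralModel-class oxidized-state basis spectrum
#' @export
oxidizedBasis <- function(object) object@oxidized

#' @describeIn SpectralModel-class named list of detector channels
#' @export
modelChannels <- function(object) object@channels

## ---------------------------------------------------------------------------
## EventTable
## ---------------------------------------------------------------------------

#' EventTable: per-cell channel intensities with optional ground truth
#'
#' One row per cell. Measured channels (scatter, MB-detecting channels or
#' spectral bins, surface markers) live in a numeric matrix, as in
#' cytometry convention. Simulated tables may also carry latent truth
#' columns (population, bacteria count, oxidized fraction); truth is kept
#' in a separate slot and is never written to FCS.
#'
#' @slot exprs numeric matrix, one row per event, named columns.
#' @slot truth data.frame with 0 rows, or one row per event (latent
#'   ground-truth columns from the simulator).
#' @slot mode \code{"conventional"} (three MB band channels) or
#'   \code{"spectral"} (wavelength-binned emission vector).
#' @slot metadata named list of free-form sample annotations.
#' @exportClass EventTable
setClass("EventTable",
  representation(exprs = "matrix", truth = "data.frame", mode = "character",
                 metadata = "list"))

setValidity("EventTable", function(object) {
  if (!is.numeric(object@exprs)) return("'exprs' must be a numeric matrix")
  if (is.null(colnames(object@exprs)) && ncol(object@exprs) > 0)
    return("'exprs' columns must be named")
  if (anyDuplicated(colnames(object@exprs)))
    return("'exprs' column names must be unique")
  if (nrow(object@truth) != 0 && nrow(object@truth) != nrow(object@exprs))
    return("'truth' must have 0 rows or one row per event")
  if (!object@mode %in% c("conventional", "spectral"))
    return("'mode' must be 'conventional' or 'spectral'")
  TRUE
})

#' Construct an EventTable
#'
#' @param exprs numeric matrix (or data.frame coerced to one) of channel
#'   values, one row per event, named columns.
#' @param truth optional per-event ground-truth data.frame.
#' @param mode \code{"conventional"} or \code{"spectral"}.
#' @param metadata named list of sample annotations.
#' @return An \linkS4class{EventTable}.
#' @examples
#' et <- EventTable(cbind(FSC = c(1, 2), SSC = c(3, 4)))
#' nrow(et)
#' @export
EventTable <- function(exprs, truth = data.frame(), mode = "conventional",
                       metadata = list()) {
  if (is.data.frame(exprs)) exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  new("EventTable", exprs = exprs, truth = truth, mode = mode,
      metadata = metadata)
}

#' @describeIn EventTable-class channel matrix accessor
#' @param object,x an \code{EventTable}
#' @export
exprs <- function(object) object@exprs

#' @describeIn EventTable-class ground-truth accessor (may have 0 rows)
#' @export
eventTruth <- function(object) object@truth

#' @describeIn EventTable-class acquisition mode accessor
#' @export
acquisitionMode <- function(object) object@mode

#' @describeIn EventTable-class channel (column) names
#' @export
channelNames <- function(object) colnames(object@exprs)

#' @describeIn EventTable-class number of events
#' @export
setMethod("nrow", "EventTable", function(x) nrow(x@exprs))

#' @describeIn EventTable-class subset events (rows) and/or channels
#' @param i,j row (event) and column (channel) indices
#' @param drop ignored; an \code{EventTable} is always returned
#' @param ... ignored
#' @export
setMethod("[", "EventTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@exprs))
  ex <- x@exprs[i, , drop = FALSE]
  if (!missing(j)) ex <- ex[, j, drop = FALSE]
  tr <- if (nrow(x@truth)) x@truth[i, , drop = FALSE] else x@truth
  if (nrow(tr)) rownames(tr) <- NULL
  rownames(ex) <- NULL
  new("EventTable", exprs = ex, truth = tr, mode = x@mode,
      metadata = x@metadata)
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events, %d channels (%s mode)%s\n",
              nrow(object@exprs), ncol(object@exprs), object@mode,
              if (nrow(object@truth)) ", with ground truth" else ""))
  cat("  channels:", paste(utils::head(colnames(object@exprs), 8),
                           collapse = " "),
      if (ncol(object@exprs) > 8) "...\n" else "\n")
})

## ---------------------------------------------------------------------------
## GateDefinition / ChannelMap
## ---------------------------------------------------------------------------

#' GateDefinition: a scatter box or 1-d threshold gate
#'
#' @slot kind \code{"scatter_box"} (rectangular gate on two channels) or
#'   \code{"threshold_1d"} (single lower cutoff on one channel).
#' @slot channels gated channel names (two for a box, one for a
#'   threshold).
#' @slot bounds for a box, numeric matrix with rows \code{lo}/\code{hi}
#'   and one column per channel; for a threshold, a single lower cutoff.
#' @slot provenance \code{"manual"} or \code{"FMO-derived"}.
#' @exportClass GateDefinition
setClass("GateDefinition",
  representation(kind = "character", channels = "character",
                 bounds = "ANY", provenance = "character"))

setValidity("GateDefinition", function(object) {
  if (!object@kind %in% c("scatter_box", "threshold_1d"))
    return("'kind' must be 'scatter_box' or 'threshold_1d'")
  if (!object@provenance %in% c("manual", "FMO-derived"))
    return("'provenance' must be 'manual' or 'FMO-derived'")
  if (object@kind == "scatter_box") {
    b <- object@bounds
    if (!is.matrix(b) || nrow(b) != 2L ||
        ncol(b) != length(object@channels))
      return("box bounds must be a 2-row matrix, one column per channel")
    if (!all(is.finite(b))) return("box bounds must be finite")
    if (any(b[1, ] >= b[2, ])) return("box bounds must satisfy lo < hi")
  } else {
    if (length(object@channels) != 1L)
      return("a 1-d threshold gates exactly one channel")
    if (length(object@bounds) != 1L || !is.finite(object@bounds))
      return("a 1-d threshold needs a single finite lower cutoff")
  }
  TRUE
})

#' Construct a rectangular scatter gate
#'
#' @param channels two channel names, e.g. \code{c("FSC", "SSC")}.
#' @param lo,hi numeric vectors of lower/upper bounds, one per channel.
#' @param provenance gate provenance label.
#' @return A \linkS4class{GateDefinition} of kind \code{"scatter_box"}.
#' @examples
#' boxGate(c("FSC", "SSC"), lo = c(3.5e4, 3.2e4), hi = c(1.5e5, 2e5))
#' @export
boxGate <- function(channels, lo, hi, provenance = "manual") {
  b <- rbind(lo = as.numeric(lo), hi = as.numeric(hi))
  colnames(b) <- channels
  new("GateDefinition", kind = "scatter_box",
      channels = as.character(channels), bounds = b,
      provenance = provenance)
}

#' Construct a 1-d lower-threshold gate
#'
#' @param channel channel name.
#' @param cutoff lower cutoff; events strictly above are inside the gate.
#' @param provenance gate provenance label.
#' @return A \linkS4class{GateDefinition} of kind \code{"threshold_1d"}.
#' @export
thresholdGate <- function(channel, cutoff, provenance = "manual") {
  new("GateDefinition", kind = "threshold_1d",
      channels = as.character(channel), bounds = as.numeric(cutoff),
      provenance = provenance)
}

setMethod("show", "GateDefinition", function(object) {
  if (object@kind == "scatter_box") {
    cat("GateDefinition (scatter_box,", object@provenance, "):\n")
    print(object@bounds)
  } else {
    cat(sprintf("GateDefinition (threshold_1d, %s): %s > %g\n",
                object@provenance, object@channels, object@bounds))
  }
})

#' ChannelMap: names of the MB-detecting channels
#'
#' Maps the three MB-detecting conventional channels and the derived
#' merged virtual MB channel to column names, plus the surface-marker
#' channels.
#'
#' @slot sources names of the three MB source channels (near-red to
#'   far-red order: AF647, AF700, APC-Cy7).
#' @slot merged name of the derived merged channel; must not collide with
#'   a source channel.
#' @slot markers surface-marker channel names.
#' @exportClass ChannelMap
setClass("ChannelMap",
  representation(sources = "character", merged = "character",
                 markers = "character"))

setValidity("ChannelMap", function(object) {
  if (length(object@sources) != 3L || anyDuplicated(object@sources))
    return("'sources' must be three distinct channel names")
  if (length(object@merged) != 1L)
    return("'merged' must be a single channel name")
  if (object@merged %in% object@sources)
    return("'merged' must differ from the source channels")
  TRUE
})

#' Construct a ChannelMap
#'
#' @param sources three distinct MB source channel names, near-red first.
#' @param merged name for the derived merged MB channel.
#' @param markers surface-marker channel names.
#' @return A \linkS4class{ChannelMap}.
#' @export
ChannelMap <- function(sources = c("AF647", "AF700", "APCCy7"),
                       merged = "MBmerged",
                       markers = c("CD45", "CD66b", "CD11b", "CD62L",
                                   "CD14", "CD16", "Siglec8")) {
  new("ChannelMap", sources = sources, merged = merged, markers = markers)
}

setMethod("show", "ChannelMap", function(object) {
  cat("ChannelMap:", paste(object@sources, collapse = " + "), "->",
      object@merged, "\n")
})

## ---------------------------------------------------------------------------
## Quantification value classes
## ---------------------------------------------------------------------------

#' ODStandardCurve: linear CFU/mL vs OD420 calibration
#'
#' @slot slope,intercept coefficients of the least-squares line
#'   CFU/mL = slope * OD + intercept; slope > 0.
#' @slot r2 coefficient of determination of the fit.
#' @slot n number of calibration points.
#' @slot odRange calibrated OD range; predictions outside it warn.
#' @exportClass ODStandardCurve
setClass("ODStandardCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 n = "integer", odRange = "numeric"))

setValidity("ODStandardCurve", function(object) {
  if (object@slope <= 0) return("'slope' must be positive")
  if (length(object@odRange) != 2L || object@odRange[1] >= object@odRange[2])
    return("'odRange' must be an increasing pair")
  TRUE
})

setMethod("show", "ODStandardCurve", function(object) {
  cat(sprintf(
    "ODStandardCurve: CFU/mL = %.4g * OD420 + %.4g (R2 = %.4f, n = %d)\n",
    object@slope, object@intercept, object@r2, object@n))
  cat(sprintf("  calibrated OD range: %.3g-%.3g\n",
              object@odRange[1], object@odRange[2]))
})

#' LabelLedger: methylene blue labeling/washing concentration ledger
#'
#' Records the MB concentration and volume of the labeling solution and
#' of every post-labeling supernatant (washes and final resuspension),
#' from which the dye mass bound to the bacteria is inferred as input
#' mass minus the sum of residual masses (mass = concentration x volume).
#'
#' @slot labelConcPct labeling concentration, percent w/v (1 percent =
#'   10 g/L).
#' @slot labelVolumeUl labeling volume, microliters.
#' @slot washConcPct,washVolumeUl residual concentrations (percent w/v)
#'   and volumes (microliters) of the washes/resuspension, in order.
#' @exportClass LabelLedger
setClass("LabelLedger",
  representation(labelConcPct = "numeric", labelVolumeUl = "numeric",
                 washConcPct = "numeric", washVolumeUl = "numeric"))

setValidity("LabelLedger", function(object) {
  if (object@labelConcPct < 0 || object@labelVolumeUl <= 0)
    return("labeling concentration must be >= 0 and volume > 0")
  if (length(object@washConcPct) != length(object@washVolumeUl))
    return("wash concentrations and volumes must align")
  if (any(object@washConcPct < 0) || any(object@washVolumeUl < 0))
    return("wash concentrations and volumes must be nonnegative")
  TRUE
})

#' Construct a LabelLedger
#'
#' @param labelConcPct labeling MB concentration (percent w/v).
#' @param labelVolumeUl labeling volume (uL).
#' @param washConcPct residual MB concentrations (percent w/v), one per
#'   wash/resuspension, in order.
#' @param washVolumeUl matching wash volumes (uL).
#' @return A \linkS4class{LabelLedger}.
#' @examples
#' LabelLedger(1, 1.3, washConcPct = c(0.5, 0.05), washVolumeUl = c(1, 1))
#' @export
LabelLedger <- function(labelConcPct, labelVolumeUl, washConcPct = numeric(),
                        washVolumeUl = numeric()) {
  new("LabelLedger", labelConcPct = labelConcPct,
      labelVolumeUl = labelVolumeUl, washConcPct = washConcPct,
      washVolumeUl = washVolumeUl)
}

setMethod("show", "LabelLedger", function(object) {
  cat(sprintf("LabelLedger: %g%% x %g uL label, %d washes\n",
              object@labelConcPct, object@labelVolumeUl,
              length(object@washConcPct)))
})
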