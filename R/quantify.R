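## Bench-side quantification: OD420 standard curve for CFU, serial
## dilution counts, bound-label mass from the washing ledger, MOI and
## order-of-magnitude comparisons.

#' Fit an OD420 standard curve for E. coli quantification
#'
#' Ordinary least squares of CFU/mL against optical density at 420 nm
#' (a wavelength absorbed by E. coli but not by methylene blue, so the
#' curve stays valid for MB-labeled bacteria). Requires at least 3
#' calibration points with distinct OD values.
#'
#' @param od OD420 readings.
#' @param cfu matched CFU/mL values.
#' @return An \linkS4class{ODStandardCurve}.
#' @examples
#' curve <- fitODCurve(c(0.1, 0.2, 0.4), c(1e8, 2e8, 4e8))
#' cfuFromOD(curve, 0.3)
#' @export
fitODCurve <- function(od, cfu) {
  stopifnot(length(od) == length(cfu))
  if (length(od) < 3)
    stop("at least 3 calibration points are required")
  if (sd(od) == 0)
    stop("OD values have zero variance; cannot fit a curve")
  fit <- lm(cfu ~ od)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted slope is not positive; calibration data look wrong")
  # summary() warns on exact calibration lines; R^2 = 1 is fine here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new("ODStandardCurve", slope = slope,
      intercept = unname(coef(fit)[1]), r2 = r2, n = length(od),
      odRange = range(od))
}

#' Predict CFU/mL from an OD420 reading
#'
#' Inverts the standard curve; readings outside the calibrated OD range
#' are extrapolations and raise a warning.
#'
#' @param curve an \linkS4class{ODStandardCurve}.
#' @param od OD420 reading(s).
#' @return Predicted CFU/mL.
#' @export
cfuFromOD <- function(curve, od) {
  stopifnot(is(curve, "ODStandardCurve"))
  if (any(od < curve@odRange[1] | od > curve@odRange[2]))
    warning("OD outside the calibrated range; extrapolating")
  curve@slope * od + curve@intercept
}

#' Inverse of the standard curve: OD420 expected for a CFU/mL
#'
#' @param curve an \linkS4class{ODStandardCurve}.
#' @param cfu CFU/mL value(s).
#' @return Corresponding OD420.
#' @export
odFromCFU <- function(curve, cfu) {
  stopifnot(is(curve, "ODStandardCurve"))
  (cfu - curve@intercept) / curve@slope
}

#' CFU/mL from a serial-dilution plate count
#'
#' \code{colonies x dilution_factor / plated_volume_mL}.
#'
#' @param colonies colony count (>= 0).
#' @param dilutionFactor total dilution factor (>= 1).
#' @param platedVolumeMl plated volume in mL (> 0).
#' @return CFU/mL.
#' @examples
#' cfuFromDilution(37, 1e6, 0.1)  # 3.7e8
#' @export
cfuFromDilution <- function(colonies, dilutionFactor, platedVolumeMl) {
  stopifnot(all(colonies >= 0), all(dilutionFactor >= 1))
  if (any(platedVolumeMl <= 0)) stop("plated volume must be positive")
  colonies * dilutionFactor / platedVolumeMl
}

# percent w/v -> grams per microliter (1% w/v = 1 g/100 mL = 1e-5 g/uL)
.pctWvToGramsPerUl <- function(pct) pct * 1e-5

#' Mass of methylene blue in a solution (mass = concentration x volume)
#'
#' @param concPct MB concentration, percent w/v (1 percent = 10 g/L).
#' @param volumeUl volume in microliters.
#' @return Mass in grams.
#' @examples
#' mbMass(1, 1)  # 1e-5 g = 10 ug
#' @export
mbMass <- function(concPct, volumeUl) {
  stopifnot(all(concPct >= 0), all(volumeUl >= 0))
  .pctWvToGramsPerUl(concPct) * volumeUl
}

#' MB mass bound to bacteria from the labeling/washing ledger
#'
#' The dye bound to the labeled bacteria is inferred as the input label
#' mass minus the residual mass recovered across all post-labeling
#' supernatants (washes and resuspension), with mass = concentration x
#' volume throughout. Residuals exceeding the input signal a ledger
#' inconsistency and raise an error.
#'
#' @param ledger a \linkS4class{LabelLedger}.
#' @return Bound MB mass in grams (nonnegative).
#' @examples
#' led <- LabelLedger(1, 1.3, washConcPct = 1, washVolumeUl = 1.3)
#' mbBoundMass(led)  # 0: residuals equal input
#' @export
mbBoundMass <- function(ledger) {
  stopifnot(is(ledger, "LabelLedger"))
  input <- mbMass(ledger@labelConcPct, ledger@labelVolumeUl)
  residual <- sum(mbMass(ledger@washConcPct, ledger@washVolumeUl))
  bound <- input - residual
  if (bound < -1e-18)
    stop("residual MB mass exceeds the input mass; ledger inconsistent")
  max(bound, 0)
}

#' Order-of-magnitude difference between two positive quantities
#'
#' \code{round(log10(a / b))} to the nearest integer; \code{a} and
#' \code{b} must be in the same units.
#'
#' @param a,b positive values in common units.
#' @return Integer order-of-magnitude difference (antisymmetric in its
#'   arguments).
#' @examples
#' ordersOfMagnitude(1e-3, 1e-5)     # 2
#' ordersOfMagnitude(70e-3, 1e-12)   # 11 (70 mg vs 1 pg, in grams)
#' @export
ordersOfMagnitude <- function(a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("both quantities must be positive")
  as.integer(round(log10(a / b)))
}

#' Multiplicity of infection
#'
#' @param bacteria number of bacteria.
#' @param cells number of cells (> 0).
#' @return MOI = bacteria / cells.
#' @examples
#' computeMOI(5e8, 5e6)  # 100
#' @export
computeMOI <- function(bacteria, cells) {
  stopifnot(all(bacteria >= 0))
  if (any(cells <= 0)) stop("cell count must be positive")
  bacteria / cells
}
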