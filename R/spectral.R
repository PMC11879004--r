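## Two-state methylene blue spectral model and spectrum-level operations.
##
## Methylene blue (MB) emission inside phagocytes is treated as a convex
## mixture of two fixed basis spectra: a reduced state peaking at 696 nm
## (the primary emission peak) and an oxidation-shifted state peaking at
## the 760 nm shoulder. The mixture weight rho in [0, 1] (the oxidized
## fraction) is the latent quantity behind the observed "red shift" of MB
## fluorescence during phagolysosomal oxidation.

# Log-normal-in-wavelength shape constants, calibrated once so that each
# basis places >= 5% of its grid mass in each of the three detector bands
# (keeps all channels informative for unmixing).
.MB_GRID <- seq(650, 820, by = 1)
.MB_OFFSET <- 600            # nm subtracted before taking logs
.MB_RED_PEAK <- 696          # nm, primary emission peak (reduced state)
.MB_OXI_PEAK <- 760          # nm, shoulder emission peak (oxidized state)
.MB_RED_SIGMA <- 0.35
.MB_OXI_SIGMA <- 0.55
.MB_ABS_PEAK <- 665          # nm, absorbance maximum of MB

# Unimodal log-normal-shaped curve on a wavelength grid with the mode
# pinned at `peak` nm; returned sum-normalized.
.lognormalBasis <- function(peak, sigma, grid = .MB_GRID,
                            offset = .MB_OFFSET) {
  x <- grid - offset
  mu <- log(peak - offset) + sigma^2   # mode of lognormal = exp(mu - s^2)
  y <- dlnorm(x, meanlog = mu, sdlog = sigma)
  EmissionSpectrum(grid, y / sum(y))
}

#' Default two-state methylene blue spectral model
#'
#' Builds the package's default \linkS4class{SpectralModel}: reduced and
#' oxidized emission bases on a 650-820 nm grid at 1 nm steps (modes 696
#' and 760 nm), the 665 nm absorbance peak, and the three red-laser
#' detector channels AF647 (655-685 nm), AF700 (705-750 nm) and APC-Cy7
#' (750-810 nm) whose merger spans 655-810 nm.
#'
#' @param gains named numeric of length 3, multiplicative detector gains
#'   for AF647/AF700/APC-Cy7 (detector voltages are modeled as pure
#'   gains; default all 1).
#' @return A \linkS4class{SpectralModel}.
#' @examples
#' m <- defaultSpectralModel()
#' findPeak(reducedBasis(m))   # 696
#' findPeak(oxidizedBasis(m))  # 760
#' @export
defaultSpectralModel <- function(gains = c(AF647 = 1, AF700 = 1,
                                           APCCy7 = 1)) {
  stopifnot(length(gains) == 3, all(gains > 0))
  channels <- list(
    AF647  = BandPassChannel("AF647", 655, 685, gain = gains[[1]]),
    AF700  = BandPassChannel("AF700", 705, 750, gain = gains[[2]]),
    APCCy7 = BandPassChannel("APCCy7", 750, 810, gain = gains[[3]]))
  new("SpectralModel",
      reduced = .lognormalBasis(.MB_RED_PEAK, .MB_RED_SIGMA),
      oxidized = .lognormalBasis(.MB_OXI_PEAK, .MB_OXI_SIGMA),
      absorbancePeak = .MB_ABS_PEAK, channels = channels)
}

#' Sum-normalize a spectrum
#'
#' Divides each data point of the emission curve by the sum of all data
#' points, so the returned intensities sum to 1. This is the correction
#' that removes overall-brightness differences between conditions and
#' allows side-by-side comparison of MB emission spectra.
#'
#' @param s an \linkS4class{EmissionSpectrum} with positive total
#'   intensity.
#' @return An \linkS4class{EmissionSpectrum} on the same grid whose
#'   intensities sum to 1; the shape (ratios between points) is
#'   unchanged.
#' @examples
#' s <- EmissionSpectrum(c(650, 660, 670, 680), c(1, 3, 4, 2))
#' intensity(normalizeSpectrum(s))  # 0.1 0.3 0.4 0.2
#' @export
normalizeSpectrum <- function(s) {
  stopifnot(is(s, "EmissionSpectrum"))
  tot <- sum(s@intensity)
  if (tot <= 0)
    stop("cannot normalize a degenerate (all-zero) spectrum")
  EmissionSpectrum(s@wavelength, s@intensity / tot)
}

#' Find the peak (modal) wavelength of a spectrum
#'
#' Returns the wavelength of the global intensity maximum. Ties are
#' broken toward the shortest wavelength; a flat spectrum tie-breaks to
#' the grid start with a warning.
#'
#' @param s an \linkS4class{EmissionSpectrum}.
#' @return Peak wavelength in nm.
#' @examples
#' findPeak(reducedBasis(defaultSpectralModel()))  # 696
#' @export
findPeak <- function(s) {
  stopifnot(is(s, "EmissionSpectrum"))
  y <- s@intensity
  if (sum(y) <= 0)
    stop("cannot locate a peak in a degenerate (all-zero) spectrum")
  if (max(y) == min(y))
    warning("flat spectrum: peak tie-broken to the grid start")
  s@wavelength[which.max(y)]   # which.max takes the first (shortest) tie
}

#' Integrate a spectrum over a detector band-pass window
#'
#' Trapezoidal integration of the spectrum over \code{[lo, hi]} nm (with
#' linear interpolation at the window boundaries), multiplied by the
#' channel gain. Additive over disjoint sub-windows and linear in both
#' the intensities and the gain. A window with no overlap with the grid
#' returns 0 with a warning.
#'
#' @param s an \linkS4class{EmissionSpectrum}.
#' @param channel a \linkS4class{BandPassChannel}.
#' @return Nonnegative band intensity (a.u.).
#' @examples
#' flat <- EmissionSpectrum(650:810, rep(1, 161))
#' bandIntegral(flat, BandPassChannel("AF647", 655, 685))  # 30
#' @export
bandIntegral <- function(s, channel) {
  stopifnot(is(s, "EmissionSpectrum"), is(channel, "BandPassChannel"))
  w <- s@wavelength; y <- s@intensity
  lo <- max(channel@lo, w[1]); hi <- min(channel@hi, w[length(w)])
  if (lo >= hi) {
    warning(sprintf("channel '%s' does not overlap the spectrum grid",
                    channel@name))
    return(0)
  }
  inside <- w > lo & w < hi
  xs <- c(lo, w[inside], hi)
  ys <- c(approx(w, y, lo)$y, y[inside], approx(w, y, hi)$y)
  area <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  channel@gain * area
}

# Per-channel band integrals of both bases: the 2 x nchannel matrix that
# makes mixture integrals linear in rho.
.basisBandMatrix <- function(model, channels = modelChannels(model)) {
  vapply(channels, function(ch)
    c(reduced = bandIntegral(model@reduced, ch),
      oxidized = bandIntegral(model@oxidized, ch)),
    numeric(2))
}

#' Mix the two basis spectra at a given oxidized fraction
#'
#' @param model a \linkS4class{SpectralModel}.
#' @param rho oxidized fraction in \code{[0, 1]}.
#' @return The sum-normalized mixture spectrum
#'   \code{(1 - rho) * reduced + rho * oxidized}.
#' @export
mixSpectra <- function(model, rho) {
  stopifnot(is(model, "SpectralModel"), length(rho) == 1L,
            rho >= 0, rho <= 1)
  EmissionSpectrum(model@reduced@wavelength,
                   (1 - rho) * model@reduced@intensity +
                     rho * model@oxidized@intensity)
}

#' Noise-free red-shift ratio at a given oxidized fraction
#'
#' Closed-form counterpart of the measured APC-Cy7:AF647 geometric-MFI
#' ratio: the ratio of the APC-Cy7 and AF647 band integrals of the
#' two-state mixture at oxidized fraction \code{rho}. Strictly increasing
#' in \code{rho} by construction of the bases and bands.
#'
#' @param model a \linkS4class{SpectralModel} whose channels include
#'   \code{AF647} and \code{APCCy7}.
#' @param rho oxidized fraction in \code{[0, 1]} (vectorized).
#' @return Dimensionless ratio(s).
#' @examples
#' m <- defaultSpectralModel()
#' predictRedshiftRatio(m, c(0, 0.5, 1))
#' @export
predictRedshiftRatio <- function(model, rho) {
  stopifnot(is(model, "SpectralModel"), all(rho >= 0), all(rho <= 1))
  B <- .basisBandMatrix(model)
  if (!all(c("AF647", "APCCy7") %in% colnames(B)))
    stop("model must define AF647 and APCCy7 channels")
  num <- (1 - rho) * B["reduced", "APCCy7"] + rho * B["oxidized", "APCCy7"]
  den <- (1 - rho) * B["reduced", "AF647"] + rho * B["oxidized", "AF647"]
  if (any(den <= 0))
    stop("degenerate model: AF647 band integral is zero")
  num / den
}

#' Estimate the oxidized fraction from an observed spectrum
#'
#' Constrained least squares on sum-normalized spectra: finds the
#' \code{rho} in \code{[0, 1]} minimizing the squared error between
#' \code{normalizeSpectrum(observed)} and the normalized two-basis
#' mixture. Because both bases are sum-normalized, the problem is linear
#' in \code{rho} and solved in closed form, then clamped to
#' \code{[0, 1]}.
#'
#' @param observed an \linkS4class{EmissionSpectrum}; resampled onto the
#'   model grid by linear interpolation if its grid differs.
#' @param model a \linkS4class{SpectralModel}.
#' @return A list with \code{rho} (estimate in \code{[0, 1]}) and
#'   \code{residual} (Euclidean norm of the fit residual).
#' @examples
#' m <- defaultSpectralModel()
#' unmixOxidizedFraction(mixSpectra(m, 0.3), m)$rho  # 0.3
#' @export
unmixOxidizedFraction <- function(observed, model) {
  stopifnot(is(observed, "EmissionSpectrum"), is(model, "SpectralModel"))
  grid <- model@reduced@wavelength
  r <- model@reduced@intensity
  o <- model@oxidized@intensity
  d <- o - r
  if (sqrt(sum(d^2)) < 1e-12)
    stop("unidentifiable model: reduced and oxidized bases are identical")
  y <- observed@intensity
  if (!isTRUE(all.equal(observed@wavelength, grid))) {
    y <- approx(observed@wavelength, y, grid, rule = 2)$y
  }
  tot <- sum(y)
  if (tot <= 0) stop("cannot unmix a degenerate (all-zero) spectrum")
  y <- y / tot
  rho <- sum((y - r) * d) / sum(d * d)
  rho <- min(max(rho, 0), 1)
  resid <- y - ((1 - rho) * r + rho * o)
  list(rho = rho, residual = sqrt(sum(resid^2)))
}

#' Map a hydrogen peroxide concentration to an oxidized fraction
#'
#' Saturating (Hill-type, coefficient 1) link between oxidant
#' concentration and the oxidized fraction of the two-state model:
#' \code{rho = conc / (conc + ec50)}. Only the direction (monotone red
#' shift with increasing peroxide) is asserted by the package; the
#' half-saturation constant is an operational parameter, not a measured
#' dose-response.
#'
#' @param conc nonnegative peroxide concentration(s), in units of
#'   \code{ec50}.
#' @param ec50 half-saturation concentration (default 1).
#' @return Oxidized fraction(s) in \code{[0, 1)}.
#' @export
peroxideOxidizedFraction <- function(conc, ec50 = 1) {
  stopifnot(all(conc >= 0), ec50 > 0)
  conc / (conc + ec50)
}

#' Default two-state absorbance model
#'
#' The same two-state mixture applied to absorbance: a reduced basis
#' peaking at the 665 nm absorbance maximum of methylene blue and an
#' oxidation-shifted basis at a longer wavelength. Used only to assert
#' the direction of the peroxide-driven absorbance change.
#'
#' @return A \linkS4class{SpectralModel} over 550-820 nm with the reduced
#'   basis peaking at 665 nm.
#' @export
defaultAbsorbanceModel <- function() {
  grid <- seq(550, 820, by = 1)
  channels <- list(
    near = BandPassChannel("near", 640, 690),
    far  = BandPassChannel("far", 700, 780))
  new("SpectralModel",
      reduced = .lognormalBasis(.MB_ABS_PEAK, 0.30, grid, offset = 500),
      oxidized = .lognormalBasis(720, 0.40, grid, offset = 500),
      absorbancePeak = .MB_ABS_PEAK, channels = channels)
}

#' Write / read a spectrum as 2-column delimited text
#'
#' Serializes a spectrum to tab-separated text with columns
#' \code{wavelength_nm} and \code{intensity}.
#'
#' @param s an \linkS4class{EmissionSpectrum}.
#' @param path file path.
#' @return \code{writeSpectrum} returns \code{path} invisibly;
#'   \code{readSpectrum} returns an \linkS4class{EmissionSpectrum}.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "EmissionSpectrum"))
  df <- data.frame(wavelength_nm = s@wavelength, intensity = s@intensity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  df <- read.delim(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectrum file must have columns 'wavelength_nm' and 'intensity'")
  EmissionSpectrum(df$wavelength_nm, df$intensity)
}
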