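## Cell-population parameterization for the synthetic event generator.

#' CellPopulationSpec: generator parameters for one leukocyte subset
#'
#' @slot name population name.
#' @slot phagocyticRate mean MBEC internalized per cell per hour per
#'   unit MOI (1/h per MOI); 0 for non-phagocytes.
#' @slot oxidationRate k_ox, first-order rate (1/h) at which the
#'   oxidized fraction of internalized MB approaches 1; set to 0 in
#'   NADPH-oxidase-deficient (CGD) neutrophils.
#' @slot autofluorescence named numeric, per-channel background
#'   geometric mean (a.u.) for the three conventional MB channels; the
#'   spectral-mode background is derived from its total.
#' @slot scatter named numeric: \code{fsc}, \code{ssc} geometric means
#'   (a.u.) and \code{sdlog} log-scale spread.
#' @slot markers named numeric, baseline surface-marker geometric means
#'   (a.u.).
#' @exportClass CellPopulationSpec
setClass("CellPopulationSpec",
  representation(name = "character", phagocyticRate = "numeric",
                 oxidationRate = "numeric", autofluorescence = "numeric",
                 scatter = "numeric", markers = "numeric"))

setValidity("CellPopulationSpec", function(object) {
  if (object@phagocyticRate < 0) return("'phagocyticRate' must be >= 0")
  if (object@oxidationRate < 0) return("'oxidationRate' must be >= 0")
  if (!all(c("fsc", "ssc", "sdlog") %in% names(object@scatter)))
    return("'scatter' needs named entries fsc, ssc, sdlog")
  if (any(object@autofluorescence < 0))
    return("autofluorescence must be nonnegative")
  TRUE
})

setMethod("show", "CellPopulationSpec", function(object) {
  cat(sprintf(
    "CellPopulationSpec '%s': phagocytic rate %g /h/MOI, k_ox %g /h\n",
    object@name, object@phagocyticRate, object@oxidationRate))
})

.popSpec <- function(name, rate, kox, af, fsc, ssc, sdlog, markers) {
  new("CellPopulationSpec", name = name, phagocyticRate = rate,
      oxidationRate = kox,
      autofluorescence = c(AF647 = af[1], AF700 = af[2], APCCy7 = af[3]),
      scatter = c(fsc = fsc, ssc = ssc, sdlog = sdlog),
      markers = markers)
}

#' Default leukocyte population parameters
#'
#' Named list of \linkS4class{CellPopulationSpec} for neutrophils,
#' eosinophils, monocytes, monocyte-derived macrophages and T/B/NK
#' lymphocytes. Phagocytic rates are ordered neutrophil > macrophage >
#' monocyte >> lymphocytes (= 0), reproducing the observed partitioning
#' of MBEC uptake across subsets; the healthy oxidation rate k_ox is
#' shared by all phagocytes. Scatter locations separate SSC-high/FSC-high
#' granulocytes from monocytes and lymphocytes; eosinophils are
#' Siglec8-high so they can be excluded downstream.
#'
#' @return Named list of \linkS4class{CellPopulationSpec}.
#' @export
cellPopulations <- function() {
  mk <- function(CD45, CD66b, CD11b, CD62L, CD14, CD16, Siglec8)
    c(CD45 = CD45, CD66b = CD66b, CD11b = CD11b, CD62L = CD62L,
      CD14 = CD14, CD16 = CD16, Siglec8 = Siglec8)
  list(
    neutrophil = .popSpec("neutrophil", rate = 2.0, kox = 0.8,
      af = c(25, 15, 8), fsc = 5.0e4, ssc = 5.0e4, sdlog = 0.15,
      markers = mk(5e3, 3e3, 2e3, 2e3, 300, 4e3, 100)),
    eosinophil = .popSpec("eosinophil", rate = 0.05, kox = 0.5,
      af = c(40, 25, 12), fsc = 5.2e4, ssc = 6.5e4, sdlog = 0.15,
      markers = mk(5e3, 2e3, 1.5e3, 2e3, 200, 500, 6e3)),
    monocyte = .popSpec("monocyte", rate = 0.4, kox = 0.6,
      af = c(35, 20, 10), fsc = 4.5e4, ssc = 1.8e4, sdlog = 0.18,
      markers = mk(6e3, 150, 3e3, 1.5e3, 5e3, 1e3, 100)),
    macrophage = .popSpec("macrophage", rate = 1.0, kox = 0.6,
      af = c(45, 28, 14), fsc = 6.5e4, ssc = 2.5e4, sdlog = 0.20,
      markers = mk(6e3, 150, 4e3, 800, 6e3, 2e3, 100)),
    T = .popSpec("T", rate = 0, kox = 0,
      af = c(15, 9, 5), fsc = 2.2e4, ssc = 7e3, sdlog = 0.18,
      markers = mk(4e3, 80, 100, 2.5e3, 60, 150, 80)),
    B = .popSpec("B", rate = 0, kox = 0,
      af = c(15, 9, 5), fsc = 2.2e4, ssc = 7e3, sdlog = 0.18,
      markers = mk(4e3, 80, 100, 2.5e3, 60, 150, 80)),
    NK = .popSpec("NK", rate = 0, kox = 0,
      af = c(15, 9, 5), fsc = 2.4e4, ssc = 8e3, sdlog = 0.18,
      markers = mk(4e3, 80, 100, 2.5e3, 60, 2e3, 80)))
}

# Label-independent activation of surface markers on E. coli contact
# (identical for MBEC and unlabeled bacteria): CD11b/CD45/CD66b up,
# CD62L shed.
.ACTIVATION_FC <- c(CD45 = 1.8, CD66b = 3, CD11b = 3, CD62L = 0.3,
                    CD14 = 1, CD16 = 1, Siglec8 = 1)

# Primed profile of extravasated blister leukocytes (applied instead of
# the coculture activation shift): CD66b/CD11b/CD45 up, CD62L down.
.BLISTER_FC <- c(CD45 = 2.5, CD66b = 4, CD11b = 4, CD62L = 0.15,
                 CD14 = 1, CD16 = 1, Siglec8 = 1)

# Per-ingested-bacterium log-scale marker modulation (receptor
# internalization with progressive phagocytosis; capped at 20 bacteria).
# Shared between ex vivo and in vivo contexts, which is what makes the
# MB-vs-marker correlation structure agree across contexts.
.UPTAKE_BETA <- c(CD45 = 0.01, CD66b = -0.04, CD11b = -0.05,
                  CD62L = -0.06, CD14 = -0.04, CD16 = -0.05, Siglec8 = 0)
.UPTAKE_CAP <- 20
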