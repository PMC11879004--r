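## Packaged study designs and on-disk study generation.

# deterministic per-sample seed derived from the global seed
.deriveSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647L)
}

.COCULTURE_MIX <- c(neutrophil = 2000, monocyte = 500, T = 500, B = 300,
                    NK = 200, eosinophil = 100)
# isolated-neutrophil tubes are acquired to a standard 10,000-event
# target, which is what makes per-sample geometric-MFI ratios stable
.NEUTROPHIL_ONLY <- c(neutrophil = 10000)
.BLOOD_MIX <- c(neutrophil = 2000, monocyte = 300, T = 400, B = 200,
                NK = 200, eosinophil = 50)
# blister cellularity over the 3-24 h time course: neutrophil influx
# peaks at 9 h and falls to ~1,000 cells by 24 h
.BLISTER_NEUTROPHILS <- c("3" = 600, "5" = 1100, "7" = 1700, "9" = 2200,
                          "24" = 1000)
.INVIVO_MOI <- 0.27          # effective local bacterial density in tissue
.ENDOTOXIN_E0 <- 10          # EU/mL at injection
.ENDOTOXIN_K <- 0.15         # 1/h clearance

.blisterMix <- function(timeH) {
  nNeu <- .BLISTER_NEUTROPHILS[[as.character(timeH)]]
  c(neutrophil = nNeu, monocyte = round(0.10 * nNeu),
    T = round(0.05 * nNeu), B = round(0.025 * nNeu),
    NK = round(0.025 * nNeu), eosinophil = round(0.02 * nNeu))
}

# --- design builders: each returns list(samples = list of SampleSpec,
#     controls = named map sample_id -> control sample_id) -------------

.designExvivo <- function(seed, mode) {
  times <- c(0, 0.25, 0.5, 0.75, 1)
  samples <- list(); idx <- 0L
  mk <- function(id, label, timeH) {
    idx <<- idx + 1L
    SampleSpec(id, .COCULTURE_MIX, mode = mode, compartment = "coculture",
               timeH = timeH, moi = 10, label = label,
               seed = .deriveSeed(seed, idx), volunteer = "V1")
  }
  samples$exvivo_ctrl <- mk("exvivo_ctrl", "unlabeled_E_coli", 1)
  for (t in times) {
    id <- sprintf("exvivo_t%03.0fmin", t * 60)
    samples[[id]] <- mk(id, "MBEC", t)
  }
  controls <- setNames(rep("exvivo_ctrl", length(samples)), names(samples))
  list(samples = samples, controls = controls)
}

.designMoi <- function(seed, mode) {
  mois <- c(1, 3, 10, 30)
  samples <- list(); idx <- 0L
  mk <- function(id, label, moi) {
    idx <<- idx + 1L
    SampleSpec(id, .COCULTURE_MIX, mode = mode, compartment = "coculture",
               timeH = 1, moi = moi, label = label,
               seed = .deriveSeed(seed, idx), volunteer = "V1")
  }
  samples$moi_ctrl <- mk("moi_ctrl", "unlabeled_E_coli", 30)
  for (m in mois) {
    id <- sprintf("moi_%03d", m)
    samples[[id]] <- mk(id, "MBEC", m)
  }
  controls <- setNames(rep("moi_ctrl", length(samples)), names(samples))
  list(samples = samples, controls = controls)
}

.designCgd <- function(seed, mode) {
  times <- c(0.25, 0.75, 1.5, 3)
  genotypes <- c("healthy", "CGD_carrier", "CGD_affected")
  samples <- list(); controls <- character(0); idx <- 0L
  for (g in genotypes) {
    ctrlId <- sprintf("cgd_%s_ctrl", g)
    idx <- idx + 1L
    samples[[ctrlId]] <- SampleSpec(ctrlId, .NEUTROPHIL_ONLY, mode = mode,
      compartment = "coculture", timeH = 3, moi = 10,
      label = "unlabeled_E_coli", genotype = g,
      seed = .deriveSeed(seed, idx), volunteer = g)
    controls[ctrlId] <- ctrlId
    for (t in times) {
      id <- sprintf("cgd_%s_t%03.0fmin", g, t * 60)
      idx <- idx + 1L
      samples[[id]] <- SampleSpec(id, .NEUTROPHIL_ONLY, mode = mode,
        compartment = "coculture", timeH = t, moi = 10, label = "MBEC",
        genotype = g, seed = .deriveSeed(seed, idx), volunteer = g)
      controls[id] <- ctrlId
    }
  }
  list(samples = samples, controls = controls)
}

# 19 volunteers, each contributing two blisters: 3+5 h (8 volunteers),
# 7+9 h (7 volunteers) or two 24 h blisters (4 volunteers) -> 38 blister
# data points, n = 7/8 per time point, plus paired blood and one
# unlabeled control per volunteer.
.designInvivo <- function(seed, mode) {
  plan <- c(rep(list(c(3, 5)), 8), rep(list(c(7, 9)), 7),
            rep(list(c(24, 24)), 4))
  samples <- list(); controls <- character(0); idx <- 0L
  for (v in seq_along(plan)) {
    vol <- sprintf("V%02d", v)
    tt <- plan[[v]]
    # fluorescence-minus-one control: the volunteer's blood leukocytes
    # cocultured with unlabeled E. coli
    ctrlId <- sprintf("invivo_%s_ctrl", vol)
    idx <- idx + 1L
    samples[[ctrlId]] <- SampleSpec(ctrlId, .BLOOD_MIX,
      mode = mode, compartment = "coculture", timeH = 1,
      moi = 5, label = "unlabeled_E_coli",
      seed = .deriveSeed(seed, idx), volunteer = vol)
    controls[ctrlId] <- ctrlId
    bloodId <- sprintf("invivo_%s_blood", vol)
    idx <- idx + 1L
    samples[[bloodId]] <- SampleSpec(bloodId, .BLOOD_MIX, mode = mode,
      compartment = "blood", timeH = tt[1], moi = 0, label = "none",
      seed = .deriveSeed(seed, idx), volunteer = vol)
    controls[bloodId] <- ctrlId
    for (k in seq_along(tt)) {
      site <- c("a", "b")[k]
      id <- sprintf("invivo_%s_blister%02.0fh_%s", vol, tt[k], site)
      idx <- idx + 1L
      samples[[id]] <- SampleSpec(id, .blisterMix(tt[k]), mode = mode,
        compartment = "blister", timeH = tt[k], moi = .INVIVO_MOI,
        label = "MBEC", seed = .deriveSeed(seed, idx), volunteer = vol,
        site = site)
      controls[id] <- ctrlId
    }
  }
  list(samples = samples, controls = controls)
}

#' Generate a complete synthetic study on disk
#'
#' Builds one of the packaged designs, renders every sample, and writes
#' per-sample FCS 3.1 files plus a tab-separated metadata sheet
#' (\code{metadata.tsv}) and per-event ground-truth table
#' (\code{truth.tsv}, never part of the FCS files). Deterministic given
#' \code{seed}.
#'
#' Designs:
#' \describe{
#'   \item{exvivo}{60-min whole-leukocyte MBEC coculture time series
#'     (0/15/30/45/60 min, MOI 10) plus an unlabeled-E. coli
#'     fluorescence-minus-one control.}
#'   \item{moi}{60-min coculture MOI titration (1/3/10/30) plus
#'     control.}
#'   \item{cgd}{isolated-neutrophil coculture series (15/45/90/180 min,
#'     MOI 10) for healthy, CGD-carrier and CGD-affected genotypes, each
#'     with its own control.}
#'   \item{invivo}{19 volunteers with paired blood and dermal suction
#'     blisters at 3/5/7/9/24 h after intradermal MBEC injection (38
#'     blister data points, 7-8 per time point), an unlabeled control
#'     per volunteer, and a monotonically clearing blister endotoxin
#'     column in the metadata.}
#' }
#'
#' @param design one of \code{"exvivo"}, \code{"invivo"}, \code{"cgd"},
#'   \code{"moi"}.
#' @param outDir output directory (created if needed).
#' @param seed integer global seed; all per-sample seeds derive from it.
#' @param mode \code{"conventional"} or \code{"spectral"}.
#' @param model a \linkS4class{SpectralModel}.
#' @param pops named list of \linkS4class{CellPopulationSpec}.
#' @param noiseCV multiplicative noise CV.
#' @return Invisibly, a list with \code{dir}, the metadata data.frame,
#'   and the list of \linkS4class{SampleSpec}.
#' @examples
#' \donttest{
#' st <- generateStudy("exvivo", file.path(tempdir(), "ex"), seed = 1)
#' }
#' @export
generateStudy <- function(design = c("exvivo", "invivo", "cgd", "moi"),
                          outDir, seed = 1L,
                          mode = c("conventional", "spectral"),
                          model = defaultSpectralModel(),
                          pops = cellPopulations(),
                          noiseCV = .DEFAULT_NOISE_CV) {
  design <- match.arg(design)
  mode <- match.arg(mode)
  if (missing(outDir) || !nzchar(outDir))
    stop("'outDir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)

  built <- switch(design,
    exvivo = .designExvivo(seed, mode),
    moi = .designMoi(seed, mode),
    cgd = .designCgd(seed, mode),
    invivo = .designInvivo(seed, mode))

  meta <- list(); truthRows <- list()
  for (id in names(built$samples)) {
    sp <- built$samples[[id]]
    et <- renderEvents(sp, model = model, pops = pops, noiseCV = noiseCV)
    file <- paste0(id, ".fcs")
    writeFCS(et, file.path(outDir, file))
    endo <- if (design == "invivo" && sp@compartment == "blister")
      .ENDOTOXIN_E0 * exp(-.ENDOTOXIN_K * sp@timeH) else NA_real_
    meta[[id]] <- data.frame(
      sample_id = id, file = file, mode = sp@mode,
      compartment = sp@compartment, time_h = sp@timeH, moi = sp@moi,
      label = sp@label, label_concentration_pct = sp@labelConcPct,
      genotype = sp@genotype, perturbation = sp@perturbation,
      volunteer = sp@volunteer, site = sp@site,
      control_id = unname(built$controls[[id]]),
      endotoxin_EU_mL = endo, seed = sp@seed)
    tr <- eventTruth(et)
    tr <- cbind(sample_id = id, event = seq_len(nrow(tr)), tr)
    truthRows[[id]] <- tr
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  write.table(metadata, file.path(outDir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dir = outDir, metadata = metadata,
                 samples = built$samples))
}
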