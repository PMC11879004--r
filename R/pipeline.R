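## Study-level orchestration: per-sample summaries, time courses,
## spectral red-shift curves, marker correlations and the full report
## bundle.

#' StudyConfig: analysis configuration for a study directory
#'
#' @slot channelMap a \linkS4class{ChannelMap}.
#' @slot gates named list of \linkS4class{GateDefinition} (population
#'   geometry).
#' @slot fmoPercentile percentile of the fluorescence-minus-one control
#'   defining the MB-high cutoff (default 99.5).
#' @slot correlationMethod rank correlation method for the MB-marker
#'   matrix (\code{"spearman"}).
#' @slot mfiGated logical; if \code{TRUE} (default) the composite MB
#'   fluorescence intensity uses the MB-high-gated population's MFI
#'   times the MB-high count, otherwise the whole population's MFI.
#' @slot seed integer seed recorded in run logs.
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(channelMap = "ChannelMap", gates = "list",
                 fmoPercentile = "numeric",
                 correlationMethod = "character", mfiGated = "logical",
                 seed = "integer"))

#' Construct a StudyConfig
#'
#' @param channelMap a \linkS4class{ChannelMap}.
#' @param gates population gate list.
#' @param fmoPercentile FMO percentile for the MB-high gate.
#' @param correlationMethod \code{"spearman"} or \code{"kendall"}.
#' @param mfiGated use the MB-high-gated MFI in the composite intensity.
#' @param seed integer seed recorded in run logs.
#' @return A \linkS4class{StudyConfig}.
#' @export
studyConfig <- function(channelMap = defaultChannelMap(),
                        gates = defaultGates(), fmoPercentile = 99.5,
                        correlationMethod = "spearman", mfiGated = TRUE,
                        seed = 1L) {
  new("StudyConfig", channelMap = channelMap, gates = gates,
      fmoPercentile = fmoPercentile,
      correlationMethod = correlationMethod, mfiGated = mfiGated,
      seed = as.integer(seed))
}

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf("StudyConfig: FMO percentile %g, %s correlation\n",
              object@fmoPercentile, object@correlationMethod))
})

# centers of the wavelength bins encoded in spectral channel names
.binBounds <- function(chn) {
  m <- regmatches(chn, regexec("^MB_([0-9]+)_([0-9]+)nm$", chn))
  ok <- lengths(m) == 3
  lo <- vapply(m[ok], function(x) as.numeric(x[2]), 0)
  hi <- vapply(m[ok], function(x) as.numeric(x[3]), 0)
  data.frame(channel = chn[ok], lo = lo, hi = hi)
}

# derive conventional-band channels from spectral bins by summation
.addVirtualBands <- function(x, map, model) {
  bb <- .binBounds(channelNames(x))
  if (!nrow(bb)) stop("spectral table has no MB_<lo>_<hi>nm bin channels")
  chans <- modelChannels(model)
  add <- vapply(seq_along(chans), function(j) {
    ch <- chans[[j]]
    cols <- bb$channel[bb$lo >= ch@lo & bb$hi <= ch@hi]
    rowSums(x@exprs[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) add <- matrix(add, nrow = 1)
  colnames(add) <- map@sources
  new("EventTable", exprs = cbind(x@exprs, add), truth = x@truth,
      mode = x@mode, metadata = x@metadata)
}

# read + prepare one sample: virtual bands (spectral), merged channel,
# population calls
.prepareSample <- function(x, config, model = defaultSpectralModel()) {
  if (is.character(x)) x <- readEvents(x)
  map <- config@channelMap
  if (acquisitionMode(x) == "spectral" &&
      !all(map@sources %in% channelNames(x)))
    x <- .addVirtualBands(x, map, model)
  if (!map@merged %in% channelNames(x)) x <- mergeMBChannel(x, map)
  list(events = x, calls = assignPopulations(x, config@gates))
}

.safeGeoMFI <- function(v) {
  if (!length(v)) return(NA_real_)
  suppressWarnings(geometricMFI(v))
}

# mean spectral-bin vector of a table subset, as an EmissionSpectrum on
# bin centers
.meanBinSpectrum <- function(x) {
  bb <- .binBounds(channelNames(x))
  y <- colMeans(x@exprs[, bb$channel, drop = FALSE])
  list(bounds = bb, values = unname(y))
}

# closed-form 1-parameter unmixing in bin space
.unmixBinned <- function(y, rB, oB) {
  rB <- rB / sum(rB); oB <- oB / sum(oB)
  d <- oB - rB
  if (sum(y) <= 0) return(list(rho = NA_real_, residual = NA_real_))
  y <- y / sum(y)
  rho <- min(max(sum((y - rB) * d) / sum(d * d), 0), 1)
  resid <- y - ((1 - rho) * rB + rho * oB)
  list(rho = rho, residual = sqrt(sum(resid^2)))
}

#' Summarize one sample against its matched control
#'
#' Produces one row per gated population: event count, merged-MB /
#' AF647 / APC-Cy7 geometric MFIs, the background-corrected
#' APC-Cy7:AF647 red-shift ratio (each channel's MFI minus the matched
#' control's MFI, so autofluorescence cannot read as a red shift; see
#' [redshiftRatio()] for the uncorrected event-level statistic), the
#' MB-high count from the control-derived
#' fluorescence-minus-one gate, the composite MB fluorescence intensity
#' (MB MFI x MB-high count, 0 when no events are MB-high), the
#' geometric-MFI fold change versus the matched control, and (spectral
#' mode) the oxidized fraction recovered from the
#' background-subtracted population-mean spectrum.
#'
#' @param events an \linkS4class{EventTable} (file path also accepted).
#' @param control the matched fluorescence-minus-one control
#'   \linkS4class{EventTable} (or path); must be supplied.
#' @param config a \linkS4class{StudyConfig}.
#' @param model a \linkS4class{SpectralModel} (used for spectral-mode
#'   band derivation and unmixing).
#' @return A data.frame, one row per population.
#' @export
summarizeSample <- function(events, control, config = studyConfig(),
                            model = defaultSpectralModel()) {
  if (missing(control) || is.null(control))
    stop("a matched fluorescence-minus-one control is required")
  map <- config@channelMap
  smp <- .prepareSample(events, config, model)
  ctl <- .prepareSample(control, config, model)
  md <- smp$events@metadata
  sid <- if (!is.null(md$sample_id)) md$sample_id else "sample"

  spectral <- acquisitionMode(smp$events) == "spectral"
  if (spectral) {
    binB <- .basisBandMatrix(model, .spectralBins(model))
  }

  pops <- intersect(c("neutrophil", "eosinophil", "monocyte",
                      "lymphocyte"), unique(smp$calls))
  rows <- lapply(pops, function(p) {
    sub <- smp$events[smp$calls == p]
    csub <- ctl$events[ctl$calls == p]
    mbMFI <- .safeGeoMFI(exprs(sub)[, map@merged])
    af647 <- .safeGeoMFI(exprs(sub)[, map@sources[1]])
    apccy7 <- .safeGeoMFI(exprs(sub)[, map@sources[3]])
    # background-corrected red-shift ratio: each channel's MFI minus
    # the matched FMO control's MFI, so cellular autofluorescence
    # (which loads the near-red channel disproportionately at low MB
    # signal) cannot masquerade as a red shift; degenerate when the MB
    # signal does not clear the background
    num <- apccy7 - .safeGeoMFI(exprs(csub)[, map@sources[3]])
    den <- af647 - .safeGeoMFI(exprs(csub)[, map@sources[1]])
    ratio <- if (is.finite(num) && is.finite(den) && den > 1 &&
                 num > 0) num / den else NA_real_
    gate <- tryCatch(fmoThreshold(csub, map@merged,
                                  config@fmoPercentile),
                     error = function(e) NULL)
    if (!is.null(gate)) {
      cls <- classifyMB(sub, gate)
      nHi <- unname(cls$counts["MBhi"])
      hiTab <- sub[cls$labels == "MBhi"]
      hiMFI <- if (config@mfiGated) .safeGeoMFI(exprs(hiTab)[, map@merged])
               else mbMFI
      mbFlInt <- if (nHi == 0) 0 else hiMFI * nHi
    } else {
      nHi <- NA_real_; mbFlInt <- NA_real_
    }
    fold <- mbMFI / .safeGeoMFI(exprs(csub)[, map@merged])
    rho <- NA_real_
    if (spectral && nrow(sub) >= 50 && nrow(csub) >= 50) {
      ms <- .meanBinSpectrum(sub)$values
      bg <- .meanBinSpectrum(csub)$values
      rho <- .unmixBinned(pmax(ms - bg, 0), binB["reduced", ],
                          binB["oxidized", ])$rho
    }
    data.frame(sample_id = sid,
               compartment = if (!is.null(md$compartment))
                 md$compartment else NA_character_,
               time_h = if (!is.null(md$time_h))
                 as.numeric(md$time_h) else NA_real_,
               population = p, n_events = nrow(sub), mb_mfi = mbMFI,
               af647_mfi = af647, apccy7_mfi = apccy7,
               redshift_ratio = ratio, mbhi_count = nHi,
               mb_fluorescence_intensity = mbFlInt, fold_change = fold,
               rho_hat = rho)
  })
  do.call(rbind, rows)
}

#' Aggregate summary rows into an ordered time course
#'
#' Rows must share one population and one compartment. Aggregates are
#' sorted by time and carry the across-volunteer mean and standard
#' deviation of the MB MFI, the MB-high count, the composite MB
#' fluorescence intensity track, and (when present in the rows) the
#' paired endotoxin clearance curve. Duplicate (volunteer, site, time)
#' rows raise an error.
#'
#' @param rows summary data.frame as from [summarizeSample()], with
#'   optional \code{volunteer}/\code{site}/\code{endotoxin_EU_mL}
#'   columns.
#' @return A data.frame with one row per time point, ordered by time.
#' @export
timecourse <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  if (length(unique(rows$population)) != 1L ||
      length(unique(rows$compartment)) != 1L)
    stop("time-course rows must share one population and compartment")
  if (!is.null(rows$volunteer)) {
    key <- paste(rows$volunteer,
                 if (!is.null(rows$site)) rows$site else "", rows$time_h)
    if (anyDuplicated(key))
      stop("duplicate (volunteer, site, time) rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  agg <- lapply(split(rows, rows$time_h), function(d) {
    data.frame(time_h = d$time_h[1], n_samples = nrow(d),
               mb_mfi_mean = mean(d$mb_mfi, na.rm = TRUE),
               mb_mfi_sd = sd(d$mb_mfi),
               mbhi_count_mean = mean(d$mbhi_count, na.rm = TRUE),
               mb_fluorescence_intensity_mean =
                 mean(d$mb_fluorescence_intensity, na.rm = TRUE),
               endotoxin_EU_mL = if (!is.null(d$endotoxin_EU_mL))
                 mean(d$endotoxin_EU_mL, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized emission curves and oxidized fractions per condition
#'
#' For each spectral-mode sample: gate to neutrophils, average the
#' per-event bin spectra, subtract the matched control's mean spectrum
#' (the autofluorescence baseline), sum-normalize, and unmix the
#' oxidized fraction against the two-state model in bin space. Each
#' returned curve sums to 1.
#'
#' @param samples named list of spectral \linkS4class{EventTable}s (or
#'   file paths).
#' @param model a \linkS4class{SpectralModel}.
#' @param control optional control \linkS4class{EventTable} (or path)
#'   used as the autofluorescence baseline for all samples.
#' @param config a \linkS4class{StudyConfig}.
#' @return A list with \code{curves} (matrix, conditions x bins, rows
#'   sum to 1) and \code{rho} (data.frame: condition, rho, residual).
#' @export
compareRedshiftSpectra <- function(samples, model = defaultSpectralModel(),
                                   control = NULL,
                                   config = studyConfig()) {
  stopifnot(is.list(samples), length(samples) > 0)
  if (is.null(names(samples)))
    names(samples) <- paste0("condition", seq_along(samples))
  prep <- lapply(samples, .prepareSample, config = config, model = model)
  modes <- vapply(prep, function(p) acquisitionMode(p$events), "")
  if (any(modes != "spectral"))
    stop("conventional-mode sample passed: ",
         paste(names(samples)[modes != "spectral"], collapse = ", "))
  bg <- NULL
  if (!is.null(control)) {
    pc <- .prepareSample(control, config, model)
    bg <- .meanBinSpectrum(pc$events[pc$calls == "neutrophil"])$values
  }
  binB <- .basisBandMatrix(model, .spectralBins(model))
  curves <- NULL; rhos <- list()
  for (nm in names(prep)) {
    p <- prep[[nm]]
    sub <- p$events[p$calls == "neutrophil"]
    ms <- .meanBinSpectrum(sub)
    y <- ms$values
    if (!is.null(bg)) y <- pmax(y - bg, 0)
    u <- .unmixBinned(y, binB["reduced", ], binB["oxidized", ])
    yn <- y / sum(y)
    curves <- rbind(curves, yn)
    rhos[[nm]] <- data.frame(condition = nm, rho = u$rho,
                             residual = u$residual)
  }
  rownames(curves) <- names(prep)
  colnames(curves) <- .binBounds(channelNames(prep[[1]]$events))$channel
  list(curves = curves, rho = do.call(rbind, rhos))
}

#' Rank correlations between the MB signal and surface markers
#'
#' @param x an \linkS4class{EventTable}, gated to one population and
#'   carrying the merged MB channel.
#' @param markers marker channel names.
#' @param mbChannel MB channel name (default the merged channel).
#' @param method rank correlation method.
#' @return Named numeric vector of correlations; a constant column
#'   yields \code{NA} for that marker.
#' @export
markerCorrelations <- function(x, markers = defaultChannelMap()@markers,
                               mbChannel = "MBmerged",
                               method = "spearman") {
  stopifnot(is(x, "EventTable"))
  if (nrow(x) < 3) stop("at least 3 events are required")
  markers <- intersect(markers, channelNames(x))
  mb <- x@exprs[, mbChannel]
  vapply(markers, function(m) {
    v <- x@exprs[, m]
    if (sd(v) == 0 || sd(mb) == 0) return(NA_real_)
    cor(mb, v, method = method)
  }, 0)
}

#' Sign-agreement score between two correlation profiles
#'
#' Fraction of markers on which two correlation vectors agree in sign
#' (computed over markers present and non-missing in both).
#'
#' @param a,b named correlation vectors.
#' @return Agreement score in \code{[0, 1]}.
#' @export
signAgreement <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(sign(a[ok]) == sign(b[ok]))
}

#' Run the full analysis over a generated study directory
#'
#' Reads \code{metadata.tsv}, processes every control first, then
#' summarizes every sample against its matched control, and writes a
#' report bundle: \code{summary.tsv}, \code{timecourse.tsv} (blister or
#' coculture neutrophil track), \code{correlations.tsv} (MB-marker rank
#' correlations per context, with the cross-context sign agreement),
#' \code{spectra.tsv} (spectral mode only) and \code{run.log}. The run
#' is deterministic: identical inputs yield byte-identical tables.
#'
#' @param studyDir directory produced by [generateStudy()] (or any
#'   directory with the same layout).
#' @param outDir output directory for the report bundle (defaults to
#'   \code{studyDir}).
#' @param config a \linkS4class{StudyConfig}.
#' @param model a \linkS4class{SpectralModel}.
#' @return Invisibly, a list with the summary data.frame, the
#'   time-course data.frame, the correlation table and output paths.
#' @export
runStudy <- function(studyDir, outDir = studyDir,
                     config = studyConfig(),
                     model = defaultSpectralModel()) {
  metaPath <- file.path(studyDir, "metadata.tsv")
  if (!file.exists(metaPath))
    stop("no metadata.tsv in ", studyDir)
  meta <- read.delim(metaPath)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  missingCtl <- setdiff(unique(meta$control_id), meta$sample_id)
  if (length(missingCtl))
    stop("study is missing its FMO control sample(s): ",
         paste(missingCtl, collapse = ", "))

  prepared <- list()
  for (i in seq_len(nrow(meta))) {
    f <- file.path(studyDir, meta$file[i])
    if (!file.exists(f))
      stop("missing event file for sample ", meta$sample_id[i], ": ", f)
    prepared[[meta$sample_id[i]]] <-
      tryCatch(.prepareSample(f, config, model), error = function(e)
        stop("sample ", meta$sample_id[i], " failed: ",
             conditionMessage(e)))
  }

  rows <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    ctl <- meta$control_id[i]
    sm <- summarizeSample(prepared[[sid]]$events,
                          prepared[[ctl]]$events, config, model)
    sm$volunteer <- meta$volunteer[i]
    sm$site <- if (!is.null(meta$site)) meta$site[i] else ""
    sm$label <- meta$label[i]
    sm$genotype <- meta$genotype[i]
    sm$endotoxin_EU_mL <- if (!is.null(meta$endotoxin_EU_mL))
      meta$endotoxin_EU_mL[i] else NA_real_
    rows[[sid]] <- sm
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  # neutrophil time course in the study's main labeled compartment;
  # omitted for designs that vary something other than time (e.g. an
  # MOI titration, where all samples share one time point)
  labeled <- summary[summary$label == "MBEC" &
                       summary$population == "neutrophil", ]
  tc <- NULL
  if (nrow(labeled)) {
    comp <- if (any(labeled$compartment == "blister")) "blister"
            else "coculture"
    sel <- labeled[labeled$compartment == comp, ]
    key <- paste(sel$volunteer, sel$site, sel$time_h)
    if (nrow(sel) && !anyDuplicated(key)) tc <- timecourse(sel)
  }

  # MB-marker correlations per context over pooled labeled neutrophils
  corTab <- NULL
  map <- config@channelMap
  for (ctx in c(ex_vivo = "coculture", in_vivo = "blister")) {
    ids <- meta$sample_id[meta$label == "MBEC" & meta$compartment == ctx]
    if (!length(ids)) next
    pool <- do.call(rbind, lapply(ids, function(sid) {
      p <- prepared[[sid]]
      exprs(p$events[p$calls == "neutrophil"])
    }))
    cc <- markerCorrelations(EventTable(pool, mode = "conventional"),
                             markers = map@markers,
                             mbChannel = map@merged,
                             method = config@correlationMethod)
    corTab <- rbind(corTab,
                    data.frame(context = names(which(
                      c(ex_vivo = "coculture",
                        in_vivo = "blister") == ctx)),
                      marker = names(cc), correlation = unname(cc)))
  }

  paths <- list(summary = file.path(outDir, "summary.tsv"))
  write.table(summary, paths$summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(tc)) {
    paths$timecourse <- file.path(outDir, "timecourse.tsv")
    write.table(tc, paths$timecourse, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(corTab)) {
    paths$correlations <- file.path(outDir, "correlations.tsv")
    write.table(corTab, paths$correlations, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (any(meta$mode == "spectral")) {
    ids <- meta$sample_id[meta$label == "MBEC"]
    sp <- compareRedshiftSpectra(
      lapply(setNames(ids, ids), function(s) prepared[[s]]$events),
      model = model, config = config)
    spTab <- cbind(data.frame(condition = rownames(sp$curves)),
                   as.data.frame(sp$curves), row.names = NULL)
    paths$spectra <- file.path(outDir, "spectra.tsv")
    write.table(spTab, paths$spectra, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$rho <- file.path(outDir, "rho.tsv")
    write.table(sp$rho, paths$rho, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log <- c(sprintf("mbecflow %s", as.character(packageVersion("mbecflow"))),
           sprintf("R %s", getRversion()),
           sprintf("study: %s", normalizePath(studyDir)),
           sprintf("samples: %d", nrow(meta)),
           sprintf("config seed: %d", config@seed),
           sprintf("fmo percentile: %g", config@fmoPercentile))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(list(summary = summary, timecourse = tc,
                 correlations = corTab, paths = paths))
}
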