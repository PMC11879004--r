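## Minimal FCS 3.1 reader/writer.
##
## List-mode, 32-bit float, little-endian ($DATATYPE F, $MODE L,
## $BYTEORD 1,2,3,4), no analysis segment, no spillover keyword
## (compensation is out of scope; simulated data are spillover-free).
## Ground-truth columns of simulated tables are never written to FCS.

.FCS_DELIM <- "/"

.fcsKeywordBlock <- function(kw) {
  esc <- function(x) gsub(.FCS_DELIM, paste0(.FCS_DELIM, .FCS_DELIM),
                          x, fixed = TRUE)
  paste0(.FCS_DELIM,
         paste0(vapply(names(kw), esc, ""), .FCS_DELIM,
                vapply(unlist(kw), esc, ""), .FCS_DELIM,
                collapse = ""))
}

#' Write an EventTable as an FCS 3.1 file
#'
#' Writes the measured channels (never the latent truth columns) as an
#' FCS 3.1 list-mode file with 32-bit little-endian floats. Sample
#' annotations from \code{metadata(x)} are stored as non-standard
#' keywords.
#'
#' @param x an \linkS4class{EventTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  ex <- x@exprs
  npar <- ncol(ex); ntot <- nrow(ex)
  kw <- list(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    # placeholders sized like the final zero-padded offsets
    "$BEGINDATA" = "00000000", "$ENDDATA" = "00000000",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
    "MBECFLOW_MODE" = x@mode)
  for (j in seq_len(npar)) {
    rng <- max(1, ceiling(max(ex[, j], 0, na.rm = TRUE)))
    kw[[sprintf("$P%dN", j)]] <- colnames(ex)[j]
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- as.character(rng)
  }
  md <- x@metadata
  for (nm in names(md)) {
    if (is.atomic(md[[nm]]) && length(md[[nm]]) == 1L)
      kw[[paste0("MBECFLOW_", toupper(nm))]] <- as.character(md[[nm]])
  }
  headerLen <- 58L
  # TEXT length is invariant to the offset values because $BEGINDATA and
  # $ENDDATA are zero-padded to 8 digits.
  textLen <- nchar(.fcsKeywordBlock(kw), type = "bytes")
  textBeg <- headerLen
  textEnd <- textBeg + textLen - 1L
  dataBeg <- textEnd + 1L
  dataEnd <- dataBeg + 4L * npar * ntot - 1L
  kw[["$BEGINDATA"]] <- sprintf("%08d", dataBeg)
  kw[["$ENDDATA"]] <- sprintf("%08d", dataEnd)
  text <- .fcsKeywordBlock(kw)
  pad8 <- function(n) formatC(n, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", pad8(textBeg), pad8(textEnd),
                   if (dataEnd <= 99999999) pad8(dataBeg) else pad8(0),
                   if (dataEnd <= 99999999) pad8(dataEnd) else pad8(0),
                   pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(ex)), con, size = 4, endian = "little")
  invisible(path)
}

.parseFCSText <- function(txt) {
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  # keyword names and values never contain the delimiter in files this
  # package writes, so a plain split suffices
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kv <- parts[seq(2, length(parts), by = 2)]
  names(kv) <- parts[seq(1, length(parts), by = 2)]
  as.list(kv)
}

#' Read an FCS 3.1 file into an EventTable
#'
#' Supports the dialect written by [writeFCS()] and any FCS 3.0/3.1 file
#' with list-mode 32-bit float data. A truncated data segment raises an
#' error rather than returning a partial read.
#'
#' @param path path to an FCS file.
#' @return An \linkS4class{EventTable} (without ground truth).
#' @export
readFCS <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L || substr(header, 1, 3) != "FCS")
    stop("not an FCS file (truncated or bad header): ", path)
  off <- function(i) as.integer(trimws(substr(header, 11 + 8 * (i - 1),
                                              10 + 8 * i)))
  textBeg <- off(1); textEnd <- off(2)
  if (is.na(textBeg) || is.na(textEnd) || textEnd <= textBeg ||
      textEnd >= sz)
    stop("corrupt FCS header offsets in ", path)
  seek(con, textBeg)
  kw <- .parseFCSText(readChar(con, textEnd - textBeg + 1L,
                               useBytes = TRUE))
  need <- c("$PAR", "$TOT", "$DATATYPE", "$MODE")
  if (!all(need %in% names(kw)))
    stop("FCS text segment missing required keywords in ", path)
  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L")
    stop("only list-mode float FCS data are supported")
  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  dataBeg <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(dataBeg) || dataBeg == 0) dataBeg <- off(3)
  n <- npar * ntot
  if (dataBeg + 4 * n - 1 > sz)
    stop("truncated FCS data segment in ", path)
  seek(con, dataBeg)
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  vals <- readBin(con, "numeric", n = n, size = 4, endian = endian)
  if (length(vals) < n) stop("truncated FCS data segment in ", path)
  ex <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(ex) <- vapply(seq_len(npar), function(j) {
    nm <- kw[[sprintf("$P%dN", j)]]
    if (is.null(nm)) sprintf("P%d", j) else nm
  }, "")
  mode <- kw[["MBECFLOW_MODE"]]
  if (is.null(mode)) mode <- "conventional"
  md <- kw[grep("^MBECFLOW_", names(kw))]
  names(md) <- tolower(sub("^MBECFLOW_", "", names(md)))
  md$mode <- NULL
  EventTable(ex, mode = mode, metadata = md)
}

#' Read events from FCS or delimited text
#'
#' Dispatches on file extension: \code{.fcs} files go through
#' [readFCS()]; \code{.tsv}/\code{.txt} files are read as tab-separated
#' tables whose numeric columns become channels (the documented tabular
#' fallback, numerically equivalent up to 32-bit float rounding in the
#' FCS path). If a \linkS4class{ChannelMap} is supplied, its source
#' channels must be present; a missing channel raises an error naming
#' it.
#'
#' @param path event file path.
#' @param channelMap optional \linkS4class{ChannelMap} to validate
#'   against.
#' @return An \linkS4class{EventTable}.
#' @export
readEvents <- function(path, channelMap = NULL) {
  ext <- tolower(tools::file_ext(path))
  et <- if (ext == "fcs") {
    readFCS(path)
  } else if (ext %in% c("tsv", "txt")) {
    df <- read.delim(path, check.names = FALSE)
    num <- vapply(df, is.numeric, TRUE)
    EventTable(as.matrix(df[num]))
  } else {
    stop("unsupported event file type: ", path)
  }
  if (!is.null(channelMap)) {
    missing <- setdiff(channelMap@sources, channelNames(et))
    if (length(missing))
      stop("event file ", path, " is missing required channel(s): ",
           paste(missing, collapse = ", "))
  }
  et
}

#' Write an EventTable as tab-separated text
#'
#' The tabular counterpart of [writeFCS()] (full double precision, no
#' truth columns).
#'
#' @param x an \linkS4class{EventTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEventsTSV <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  write.table(as.data.frame(x@exprs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
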